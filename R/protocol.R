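#' Real-time radial acquisition protocol
#'
#' Bundles the acquisition constants of the simulated real-time radial bSSFP
#' protocol: image matrix, field of view, spokes acquired per frame, the spoke
#' count regarded as fully sampling k-space, repetition time, the temporal
#' spacing of the synthetic real-time frames, the training crop and the fixed
#' frame count all network inputs are interpolated to.
#'
#' Defaults mirror a 1.5 T single-shot radial bSSFP real-time protocol:
#' 192 x 192 matrix over a 320 mm FOV (1.67 mm pixels), 14 spokes per frame
#' against 182 fully-sampling spokes (13x acceleration), TR 2.8 ms, frames
#' 36.4 ms apart, 128 x 128 training crop, 20 frames after temporal
#' interpolation. The frame spacing is a protocol constant, not derived from
#' \code{spokes_per_frame * tr_ms}.
#'
#' @param matrix_size Image pixels per side.
#' @param fov_mm Field of view in mm.
#' @param spokes_per_frame Radial spokes acquired per reconstructed frame.
#' @param full_sampling_spokes Spokes required to fully sample k-space.
#' @param tr_ms Repetition time in ms.
#' @param frame_spacing_ms Temporal spacing of synthetic real-time frames (ms).
#' @param crop_size Side of the centred training crop in pixels.
#' @param n_frames_fixed Frame count after temporal interpolation.
#' @param readout_samples Samples per spoke (default 2x matrix: 2x readout
#'   oversampling, standard radial practice).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(matrix_size = 192L,
                            fov_mm = 320,
                            spokes_per_frame = 14L,
                            full_sampling_spokes = 182L,
                            tr_ms = 2.8,
                            frame_spacing_ms = 36.4,
                            crop_size = 128L,
                            n_frames_fixed = 20L,
                            readout_samples = 2L * matrix_size) {
  matrix_size <- as.integer(matrix_size)
  spokes_per_frame <- as.integer(spokes_per_frame)
  full_sampling_spokes <- as.integer(full_sampling_spokes)
  crop_size <- as.integer(crop_size)
  n_frames_fixed <- as.integer(n_frames_fixed)
  readout_samples <- as.integer(readout_samples)
  stopifnot(matrix_size > 0L, spokes_per_frame > 0L,
            full_sampling_spokes > 0L, crop_size > 0L,
            n_frames_fixed > 0L, readout_samples > 0L,
            fov_mm > 0, tr_ms > 0, frame_spacing_ms > 0)
  if (spokes_per_frame > full_sampling_spokes)
    stop("spokes_per_frame must not exceed full_sampling_spokes")
  if (crop_size > matrix_size)
    stop("crop_size must not exceed matrix_size")
  acc <- full_sampling_spokes / spokes_per_frame
  if (!is.finite(acc) || acc < 1)
    stop("acceleration must be finite and >= 1")
  structure(list(
    matrix_size = matrix_size, fov_mm = fov_mm,
    spokes_per_frame = spokes_per_frame,
    full_sampling_spokes = full_sampling_spokes,
    tr_ms = tr_ms, frame_spacing_ms = frame_spacing_ms,
    crop_size = crop_size, n_frames_fixed = n_frames_fixed,
    readout_samples = readout_samples
  ), class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Real-time radial protocol\n",
    "  matrix %d x %d, FOV %.0f mm (pixel %.2f mm)\n",
    "  %d spokes/frame, %d fully sampling (acceleration %.1fx)\n",
    "  TR %.1f ms, frame spacing %.1f ms\n",
    "  crop %d x %d, %d frames after interpolation, %d readout samples\n"),
    x$matrix_size, x$matrix_size, x$fov_mm, pixel_size_mm(x),
    x$spokes_per_frame, x$full_sampling_spokes, acceleration_factor(x),
    x$tr_ms, x$frame_spacing_ms, x$crop_size, x$crop_size,
    x$n_frames_fixed, x$readout_samples))
  invisible(x)
}

#' Acceleration (undersampling) factor of a protocol
#'
#' Ratio of fully-sampling spoke count to spokes acquired per frame;
#' 182 / 14 = 13 under the default protocol.
#'
#' @param config A [protocol_config()].
#' @return Numeric acceleration factor.
#' @export
acceleration_factor <- function(config) {
  stopifnot(inherits(config, "protocol_config"))
  config$full_sampling_spokes / config$spokes_per_frame
}

#' In-plane pixel size in mm
#' @param config A [protocol_config()].
#' @return Pixel size `fov_mm / matrix_size` in mm.
#' @export
pixel_size_mm <- function(config) {
  stopifnot(inherits(config, "protocol_config"))
  config$fov_mm / config$matrix_size
}

#' The 7th tiny golden angle
#'
#' The tiny golden angles are psi_N = 180 / (tau + N - 1) degrees with tau the
#' golden ratio (1 + sqrt(5)) / 2; N = 7 gives 180 / (tau + 6), approximately
#' 23.63 degrees. Successive spokes separated by this angle achieve
#' near-uniform incremental angular coverage of k-space with small angular
#' jumps between repetitions.
#'
#' @return The angle in degrees (double precision, unrounded).
#' @export
tiny_golden_angle <- function() {
  tau <- (1 + sqrt(5)) / 2
  180 / (tau + 6)
}

#' Generate a radial sampling trajectory
#'
#' Builds per-frame spoke angles and normalized k-space sample coordinates for
#' one of four radial schemes:
#' \describe{
#'   \item{`REG_no_rot`}{equal angular spacing `180/spokes_per_frame` within a
#'     frame (~12.9 degrees at 14 spokes), identical in every frame.}
#'   \item{`REG_rot`}{equal spacing within a frame plus an inter-frame rotation
#'     of `(180/spokes_per_frame)/acceleration` (~0.99 degrees), so that
#'     `acceleration` consecutive frames tile a fully sampled k-space.}
#'   \item{`tGA_no_rot`}{spokes separated by the 7th tiny golden angle
#'     (~23.63 degrees), the same set in every frame.}
#'   \item{`tGA_rot`}{the tiny golden angle accumulated continuously across
#'     frames; the step from the last spoke of one frame to the first spoke of
#'     the next is again the tiny golden angle.}
#' }
#' Angles accumulate mod 360 (spoke direction alternates through k-space);
#' reduce mod 180 for sampling-density arguments. 0 degrees points along +kx,
#' counter-clockwise positive. Each spoke carries `readout_samples` samples
#' uniformly spaced in radius from -0.5 up to (but excluding) +0.5
#' cycles/pixel.
#'
#' @param config A [protocol_config()].
#' @param scheme One of `"REG_no_rot"`, `"REG_rot"`, `"tGA_no_rot"`,
#'   `"tGA_rot"` (case insensitive).
#' @param n_frames Number of frames (>= 1).
#' @return An object of class `radial_trajectory` with fields `scheme`,
#'   `angles_deg` (frames x spokes matrix), `radii` (readout radii,
#'   cycles/pixel), `n_frames`, `config`.
#' @export
make_trajectory <- function(config, scheme, n_frames) {
  stopifnot(inherits(config, "protocol_config"))
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L)
  schemes <- c("REG_no_rot", "REG_rot", "tGA_no_rot", "tGA_rot")
  m <- match(tolower(scheme), tolower(schemes))
  if (is.na(m))
    stop(sprintf("unknown sampling scheme '%s'; expected one of %s",
                 scheme, paste(schemes, collapse = ", ")))
  scheme <- schemes[m]
  ns <- config$spokes_per_frame
  s <- seq_len(ns) - 1
  f <- seq_len(n_frames) - 1
  psi <- tiny_golden_angle()
  reg <- 180 / ns
  acc <- acceleration_factor(config)
  ang <- switch(scheme,
    REG_no_rot = outer(f, s, function(fi, si) si * reg),
    REG_rot    = outer(f, s, function(fi, si) si * reg + fi * reg / acc),
    tGA_no_rot = outer(f, s, function(fi, si) si * psi),
    tGA_rot    = outer(f, s, function(fi, si) (fi * ns + si) * psi)
  )
  ang <- ang %% 360
  R <- config$readout_samples
  radii <- (seq_len(R) - 1 - R / 2) / R  # [-0.5, 0.5) cycles/pixel
  structure(list(scheme = scheme, angles_deg = ang, radii = radii,
                 n_frames = n_frames, config = config),
            class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("Radial trajectory: %s, %d frames x %d spokes x %d samples\n",
              x$scheme, x$n_frames, ncol(x$angles_deg), length(x$radii)))
  invisible(x)
}

#' k-space sample coordinates for one trajectory frame
#'
#' @param traj A [make_trajectory()] result.
#' @param frame Frame index (1-based).
#' @return A `(spokes * readout_samples) x 2` matrix of (kx, ky) in
#'   cycles/pixel, sample-major within spoke.
#' @export
trajectory_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "radial_trajectory"),
            frame >= 1, frame <= traj$n_frames)
  th <- traj$angles_deg[frame, ] * pi / 180
  kx <- outer(traj$radii, cos(th))   # samples x spokes
  ky <- outer(traj$radii, sin(th))
  cbind(as.vector(kx), as.vector(ky))
}

#' Smallest number of frames tiling a fully sampled k-space
#'
#' Pools the spoke angles of the first `m` consecutive frames reduced mod 180
#' degrees and tests, for increasing `m`, whether they form the complete
#' uniform set of `full_sampling_spokes` angles spaced `180 /
#' full_sampling_spokes` apart (within `tol` degrees). Exhaustive search up to
#' `max_frames`; returns `NA` if no `m` tiles.
#'
#' @param traj A [make_trajectory()] result.
#' @param tol Angular tolerance in degrees.
#' @param max_frames Largest `m` tried (default `2 * acceleration`).
#' @return Integer `m`, or `NA_integer_`.
#' @export
frames_to_full_sampling <- function(traj, tol = 1e-6, max_frames = NULL) {
  stopifnot(inherits(traj, "radial_trajectory"))
  cfg <- traj$config
  nfull <- cfg$full_sampling_spokes
  target <- sort((seq_len(nfull) - 1) * 180 / nfull)
  if (is.null(max_frames))
    max_frames <- ceiling(2 * acceleration_factor(cfg))
  max_frames <- min(max_frames, traj$n_frames)
  for (m in seq_len(max_frames)) {
    ang <- sort(as.vector(traj$angles_deg[seq_len(m), , drop = FALSE]) %% 180)
    if (length(ang) != nfull) next
    # compare as circular sets: align to nearest target offset
    if (max(abs(ang - target)) < tol) return(m)
  }
  NA_integer_
}
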