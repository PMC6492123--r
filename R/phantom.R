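#' Cine volume container
#'
#' A 2D+time magnitude image series with spacing metadata: the unit of data
#' throughout the package. Frames are stored `(row, col, frame)`.
#'
#' @param data Numeric array `(rows, cols, frames)`, non-negative.
#' @param pixel_mm In-plane pixel spacing in mm.
#' @param frame_ms Temporal frame spacing in ms.
#' @param rr_ms Source R-R interval in ms (optional).
#' @param subject_id,slice_id Labels.
#' @return An object of class `cine_volume`.
#' @export
cine_volume <- function(data, pixel_mm, frame_ms, rr_ms = NULL,
                        subject_id = NA_character_, slice_id = NA_character_) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1))
  stopifnot(length(dim(data)) == 3, all(data >= 0), dim(data)[3] >= 1,
            pixel_mm > 0, frame_ms > 0)
  structure(list(data = data, pixel_mm = pixel_mm, frame_ms = frame_ms,
                 rr_ms = rr_ms, subject_id = subject_id, slice_id = slice_id),
            class = "cine_volume")
}

#' @export
print.cine_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Cine volume: %d x %d x %d frames, %.2f mm pixels, %.1f ms/frame%s\n",
              d[1], d[2], d[3], x$pixel_mm, x$frame_ms,
              if (!is.null(x$rr_ms)) sprintf(", R-R %.0f ms", x$rr_ms) else ""))
  invisible(x)
}

#' Parameters of the analytic cardiac phantom
#'
#' Geometry and contrast of a synthetic short-axis cine: a contracting left
#' ventricular annulus (dark myocardium around a bright blood pool), papillary
#' muscle discs moving rigidly with the wall, a right ventricular crescent,
#' and an elliptical torso with a subcutaneous fat rim, with bSSFP-like
#' bright-blood contrast. Intensities are in [0, 1]. Motion is strictly
#' periodic in the cardiac phase; an optional respiratory translation
#' (default off) breaks that periodicity when enabled.
#'
#' Defaults emulate a retrospectively gated breath-hold short-axis cine:
#' 240 matrix at 4/3 mm pixels (320 mm FOV), 40 reconstructed phases over a
#' 1000 ms R-R interval, end-diastolic LV endocardial radius 24 mm with a
#' 9 mm wall contracting by 35%.
#'
#' @param matrix Image side in pixels.
#' @param pixel_mm Pixel spacing in mm.
#' @param rr_ms R-R interval in ms.
#' @param n_phases Reconstructed cardiac phases per cycle.
#' @param lv_radius_mm End-diastolic LV endocardial radius.
#' @param wall_thickness_mm End-diastolic myocardial wall thickness.
#' @param contraction_fraction Peak fractional reduction of the endocardial
#'   radius, in (0, 1).
#' @param n_papillary Number of papillary muscle discs.
#' @param rv_crescent Logical: include the right ventricular crescent.
#' @param heart_angle_deg Orientation of the RV/septum relative to the LV.
#' @param levels Named intensity levels (`blood`, `myo`, `fat`, `muscle`,
#'   `background`) in [0, 1].
#' @param breathing_amplitude_mm,breathing_period_ms Optional respiratory
#'   translation (amplitude 0 disables it).
#' @param seed Integer seed for the per-instance texture jitter.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(matrix = 240L, pixel_mm = 320 / 240, rr_ms = 1000,
                           n_phases = 40L, lv_radius_mm = 24,
                           wall_thickness_mm = 9, contraction_fraction = 0.35,
                           n_papillary = 2L, rv_crescent = TRUE,
                           heart_angle_deg = 200,
                           levels = c(blood = 0.95, myo = 0.30, fat = 0.85,
                                      muscle = 0.45, background = 0.03),
                           breathing_amplitude_mm = 0,
                           breathing_period_ms = 4000, seed = 1L) {
  stopifnot(contraction_fraction > 0 || contraction_fraction == 0,
            contraction_fraction < 1,
            lv_radius_mm > 0, wall_thickness_mm > 0, n_phases >= 1,
            all(levels >= 0 & levels <= 1), rr_ms > 0, pixel_mm > 0)
  fov <- matrix * pixel_mm
  if (2 * (lv_radius_mm + wall_thickness_mm) > 0.9 * fov)
    stop("heart geometry exceeds the phantom matrix")
  structure(list(matrix = as.integer(matrix), pixel_mm = pixel_mm,
                 rr_ms = rr_ms, n_phases = as.integer(n_phases),
                 lv_radius_mm = lv_radius_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 contraction_fraction = contraction_fraction,
                 n_papillary = as.integer(n_papillary),
                 rv_crescent = isTRUE(rv_crescent),
                 heart_angle_deg = heart_angle_deg,
                 levels = levels,
                 breathing_amplitude_mm = breathing_amplitude_mm,
                 breathing_period_ms = breathing_period_ms,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# anti-aliased coverage of {d <= 0} with ~1 pixel smooth transition,
# d a signed distance in mm
aa_cov <- function(d, pixel_mm) {
  t <- pmin(pmax(0.5 - d / pixel_mm, 0), 1)
  t * t * (3 - 2 * t)  # smoothstep
}

paint <- function(img, cov, level) img * (1 - cov) + level * cov

#' Render one phantom frame at a given cardiac phase
#'
#' `phase` is the fraction of the cardiac cycle in [0, 1]; the rendering is
#' exactly periodic, `phase = 1` reproduces `phase = 0`. Contraction follows
#' `r_endo(phase) = r0 * (1 - cf * (1 - cos(2 pi phase)) / 2)` with the wall
#' thickening to conserve myocardial cross-sectional area.
#'
#' @param params A [phantom_params()].
#' @param phase Cardiac phase fraction.
#' @param time_ms Absolute time (only used by the optional respiratory drift).
#' @return Matrix `(matrix, matrix)` of intensities in [0, 1].
#' @export
phantom_frame <- function(params, phase, time_ms = 0) {
  p <- params
  N <- p$matrix
  px <- p$pixel_mm
  co <- (seq_len(N) - (N + 1) / 2) * px   # centred mm coordinates
  X <- matrix(co, N, N)                   # row coordinate
  Y <- matrix(co, N, N, byrow = TRUE)     # col coordinate
  lv <- p$levels
  # deterministic per-instance jitter of structure placement
  set.seed(p$seed)
  jit <- stats::runif(6, -1, 1)

  breath <- if (p$breathing_amplitude_mm > 0)
    p$breathing_amplitude_mm * sin(2 * pi * time_ms / p$breathing_period_ms) else 0

  h <- (1 - cos(2 * pi * phase)) / 2      # 0 at diastole, 1 at systole
  r_endo0 <- p$lv_radius_mm
  r_epi0 <- r_endo0 + p$wall_thickness_mm
  r_endo <- r_endo0 * (1 - p$contraction_fraction * h)
  r_epi <- sqrt(r_endo^2 + (r_epi0^2 - r_endo0^2))  # incompressible wall

  cx <- 0.06 * N * px / 4 + jit[1] * 2
  cy <- -0.02 * N * px / 4 + jit[2] * 2 + breath
  fov <- N * px

  img <- matrix(lv["background"], N, N)
  # torso ellipse + fat rim
  dt_ell <- sqrt((X / 0.46)^2 + (Y / 0.36)^2) * 0.41 - fov * 0.41
  img <- paint(img, aa_cov(dt_ell, px), lv["fat"])
  img <- paint(img, aa_cov(dt_ell + 0.03 * fov, px), lv["muscle"])

  dx <- X - cx; dy <- Y - cy
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)

  # RV crescent: bright pool outside the septal side of the LV epicardium
  if (p$rv_crescent) {
    ha <- p$heart_angle_deg * pi / 180
    rvc <- 0.9 * r_epi
    rx <- cx + cos(ha) * (r_epi + 0.35 * rvc)
    ry <- cy + sin(ha) * (r_epi + 0.35 * rvc)
    rv_scale <- 1 - 0.5 * p$contraction_fraction * h
    d_rv <- sqrt((X - rx)^2 + (Y - ry)^2) - rvc * rv_scale
    sept <- r - (r_epi + 0.30 * p$wall_thickness_mm)  # keep a septal wall
    cov_rv <- aa_cov(d_rv, px) * aa_cov(-sept, px)
    img <- paint(img, cov_rv, lv["blood"])
  }

  # LV myocardium (epicardial disc), then blood pool (endocardial disc)
  img <- paint(img, aa_cov(r - r_epi, px), lv["myo"])
  img <- paint(img, aa_cov(r - r_endo, px), lv["blood"])

  # papillary muscles: discs riding on the endocardial border
  if (p$n_papillary > 0) {
    for (k in seq_len(p$n_papillary)) {
      ak <- 2 * pi * (k - 0.25) / p$n_papillary + 0.5 + 0.3 * jit[3]
      pr <- 0.16 * r_endo   # papillary discs scale with the cavity
      pd <- r_endo - 0.9 * pr
      pxc <- cx + pd * cos(ak); pyc <- cy + pd * sin(ak)
      d_pap <- sqrt((X - pxc)^2 + (Y - pyc)^2) - pr
      img <- paint(img, aa_cov(d_pap, px), lv["myo"])
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a retrospectively gated synthetic cine
#'
#' Renders `n_phases` frames over one cardiac cycle (phases `0, 1/n, ...,
#' (n-1)/n`); frame spacing is `rr_ms / n_phases`. Deterministic given the
#' params seed; exactly periodic (a full-cycle return frame equals frame 1)
#' when respiratory motion is disabled.
#'
#' @param params A [phantom_params()].
#' @param subject_id,slice_id Labels passed through to the volume.
#' @return A [cine_volume()].
#' @export
make_gated_cine <- function(params, subject_id = "phantom", slice_id = "s1") {
  p <- params
  dt <- p$rr_ms / p$n_phases
  frames <- vapply(seq_len(p$n_phases) - 1,
                   function(i) phantom_frame(p, i / p$n_phases, i * dt),
                   matrix(0, p$matrix, p$matrix))
  cine_volume(frames, pixel_mm = p$pixel_mm, frame_ms = dt, rr_ms = p$rr_ms,
              subject_id = subject_id, slice_id = slice_id)
}

# bilinear resample of a matrix onto an n x n grid covering the same field
resize_bilinear <- function(img, n) {
  m <- nrow(img)
  if (m == n) return(img)
  # align physical field: target centre (j - 0.5)/n of the field maps to
  # continuous 1-based source pixel-centre coordinate (j - 0.5) * m/n + 0.5
  src <- (seq_len(n) - 0.5) * m / n + 0.5
  i0 <- pmin(pmax(floor(src), 1), m)
  i1 <- pmin(i0 + 1, m)
  wfr <- pmin(pmax(src - i0, 0), 1)
  a <- img[i0, , drop = FALSE] * (1 - wfr) + img[i1, , drop = FALSE] * wfr
  b <- a[, i0, drop = FALSE] * (1 - matrix(wfr, n, n, byrow = TRUE)) +
       a[, i1, drop = FALSE] * matrix(wfr, n, n, byrow = TRUE)
  b
}

# linear interpolation of a (H, W, T) stack onto new frame times (ms),
# wrapping periodically when `period_ms` is given, else clamped at the ends
interp_time <- function(stack, t_src, t_new, period_ms = NULL) {
  d <- dim(stack)
  out <- array(0, c(d[1], d[2], length(t_new)))
  for (j in seq_along(t_new)) {
    t <- t_new[j]
    if (!is.null(period_ms)) t <- t %% period_ms
    if (t <= t_src[1]) {
      lo <- 1; hi <- 1; w <- 0
    } else if (t >= t_src[length(t_src)]) {
      if (!is.null(period_ms)) {
        lo <- length(t_src); hi <- 1
        span <- period_ms - t_src[length(t_src)] + t_src[1]
        w <- (t - t_src[length(t_src)]) / span
      } else {
        lo <- length(t_src); hi <- lo; w <- 0
      }
    } else {
      lo <- max(which(t_src <= t)); hi <- lo + 1
      w <- (t - t_src[lo]) / (t_src[hi] - t_src[lo])
    }
    out[, , j] <- stack[, , lo] * (1 - w) + stack[, , hi] * w
  }
  out
}

#' Convert a gated cine to synthetic real-time frames
#'
#' Bilinearly resamples each frame onto the protocol matrix and linearly
#' resamples in time onto points `frame_spacing_ms` apart. The output frame
#' count is `floor(rr_ms / frame_spacing_ms)`; times past the last gated
#' phase wrap periodically through the cardiac cycle. The result is the
#' artifact-free ground truth for training.
#'
#' @param cine A [cine_volume()] with known `rr_ms` and >= 2 frames.
#' @param config A [protocol_config()].
#' @return A [cine_volume()] with `config$matrix_size` square frames.
#' @export
gated_to_realtime <- function(cine, config) {
  stopifnot(inherits(cine, "cine_volume"), inherits(config, "protocol_config"))
  if (is.null(cine$rr_ms)) stop("cine must carry an R-R interval (rr_ms)")
  d <- dim(cine$data)
  if (d[3] < 2) stop("cine must have at least 2 frames")
  nf <- floor(cine$rr_ms / config$frame_spacing_ms)
  if (nf < 1) stop("R-R interval shorter than one real-time frame")
  N <- config$matrix_size
  sp <- vapply(seq_len(d[3]), function(f) resize_bilinear(cine$data[, , f], N),
               matrix(0, N, N))
  t_src <- (seq_len(d[3]) - 1) * cine$frame_ms
  t_new <- (seq_len(nf) - 1) * config$frame_spacing_ms
  rt <- interp_time(sp, t_src, t_new, period_ms = cine$rr_ms)
  cine_volume(rt, pixel_mm = config$fov_mm / N,
              frame_ms = config$frame_spacing_ms, rr_ms = cine$rr_ms,
              subject_id = cine$subject_id, slice_id = cine$slice_id)
}

#' Min-max normalize a 3D data set to [0, 1]
#'
#' Per whole 3D (2D+time) data set, not per frame. Constant-valued inputs map
#' to all zeros. Idempotent.
#'
#' @param x Array or [cine_volume].
#' @return Same type, intensities in [0, 1].
#' @export
normalize_minmax <- function(x) {
  is_cine <- inherits(x, "cine_volume")
  a <- if (is_cine) x$data else x
  rng <- range(a)
  a <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) else a * 0
  if (is_cine) { x$data <- a; x } else a
}

crop_center <- function(stack, crop, offset = c(0, 0)) {
  d <- dim(stack)
  r0 <- floor((d[1] - crop) / 2) + 1 + offset[1]
  c0 <- floor((d[2] - crop) / 2) + 1 + offset[2]
  if (r0 < 1 || c0 < 1 || r0 + crop - 1 > d[1] || c0 + crop - 1 > d[2])
    stop("crop window exceeds image bounds")
  stack[r0:(r0 + crop - 1), c0:(c0 + crop - 1), , drop = FALSE]
}

#' Prepare a paired (truth, aliased) training sample
#'
#' Applies the synthetic-data pipeline to a real-time ground-truth cine: the
#' aliased branch is the magnitude of the regridding reconstruction of the
#' radially undersampled forward encoding (`|adjoint(forward(truth))|` with
#' ramp density compensation); both branches are then centre-cropped to
#' `crop_size` (shifted by `crop_offset`), linearly interpolated through time
#' to `n_frames_fixed` frames (endpoints pinned to the first and last source
#' frames) and min-max normalized to [0, 1].
#'
#' @param truth_rt Ground-truth real-time [cine_volume()] (matrix equal to
#'   `config$matrix_size`).
#' @param traj A trajectory with at least as many frames as `truth_rt`.
#' @param config A [protocol_config()].
#' @param crop_offset Integer `(rows, cols)` shift of the crop window.
#' @return List with [cine_volume] elements `truth` and `aliased`, both
#'   `(crop_size, crop_size, n_frames_fixed)`.
#' @export
prepare_pair <- function(truth_rt, traj, config, crop_offset = c(0L, 0L)) {
  stopifnot(inherits(truth_rt, "cine_volume"), inherits(config, "protocol_config"))
  d <- dim(truth_rt$data)
  stopifnot(d[1] == config$matrix_size, d[2] == config$matrix_size)
  nf <- d[3]
  if (traj$n_frames < nf)
    stop("trajectory has fewer frames than the ground truth")
  ksp <- forward_radial(truth_rt$data, traj)
  ksp$samples <- ksp$samples[, , seq_len(nf), drop = FALSE]
  aliased <- Mod(adjoint_radial(ksp, density_comp = "on"))
  prep <- function(stack) {
    cr <- crop_center(stack, config$crop_size, crop_offset)
    t_src <- seq_len(nf) - 1
    t_new <- if (config$n_frames_fixed > 1)
      seq(0, nf - 1, length.out = config$n_frames_fixed) else 0
    normalize_minmax(interp_time(cr, t_src, t_new))
  }
  mk <- function(a) cine_volume(a, pixel_mm = truth_rt$pixel_mm,
                                frame_ms = truth_rt$frame_ms * max(nf - 1, 1) /
                                  max(config$n_frames_fixed - 1, 1),
                                rr_ms = truth_rt$rr_ms,
                                subject_id = truth_rt$subject_id,
                                slice_id = truth_rt$slice_id)
  list(truth = mk(prep(truth_rt$data)), aliased = mk(prep(aliased)))
}

#' Build a reproducible benchmark of paired phantom data sets
#'
#' Draws per-subject phantom parameters from documented physiological ranges
#' (R-R interval uniform on `rr_range_ms`, LV radius, wall thickness,
#' contraction fraction and heart orientation jittered per subject; small
#' per-slice geometric jitter), renders the gated cine, converts it to
#' synthetic real-time frames and prepares the (truth, aliased) pair for the
#' requested sampling scheme. One master seed controls everything; the
#' returned manifest identifies each pair.
#'
#' @param n_subjects,slices_per_subject Counts.
#' @param config A [protocol_config()].
#' @param scheme Sampling scheme name (see [make_trajectory()]).
#' @param seed Master seed.
#' @param phantom_matrix Gated phantom matrix (resampled down to the protocol
#'   matrix).
#' @param n_phases Gated phases per cycle.
#' @param rr_range_ms Range the per-subject R-R interval is drawn from.
#' @return List with `pairs` (list of `prepare_pair()` outputs), `truths_rt`
#'   (the uncropped real-time truths) and `manifest` (data frame).
#' @export
make_dataset <- function(n_subjects, slices_per_subject = 1L, config,
                         scheme = "tGA_rot", seed = 1L,
                         phantom_matrix = 240L, n_phases = 20L,
                         rr_range_ms = c(600, 1200)) {
  stopifnot(n_subjects >= 1)
  set.seed(as.integer(seed))
  fov <- config$fov_mm
  max_frames <- floor(rr_range_ms[2] / config$frame_spacing_ms) + 1
  traj <- make_trajectory(config, scheme, max_frames)
  pairs <- list(); truths <- list(); rows <- list()
  k <- 0
  for (s in seq_len(n_subjects)) {
    rr <- stats::runif(1, rr_range_ms[1], rr_range_ms[2])
    base_r <- stats::runif(1, 0.055, 0.085) * fov
    wall <- stats::runif(1, 0.25, 0.4) * base_r
    cf <- stats::runif(1, 0.25, 0.45)
    ang <- stats::runif(1, 0, 360)
    lev_j <- stats::runif(3, -0.05, 0.05)
    for (sl in seq_len(slices_per_subject)) {
      k <- k + 1
      sl_seed <- as.integer((seed * 1000L + s * 37L + sl) %% .Machine$integer.max)
      pp <- phantom_params(
        matrix = phantom_matrix, pixel_mm = fov / phantom_matrix,
        rr_ms = rr, n_phases = n_phases,
        lv_radius_mm = base_r * (1 - 0.05 * (sl - 1)),
        wall_thickness_mm = wall, contraction_fraction = cf,
        heart_angle_deg = ang,
        levels = c(blood = min(0.95 + lev_j[1], 1), myo = 0.30 + lev_j[2],
                   fat = 0.85 + lev_j[3], muscle = 0.45, background = 0.03),
        seed = sl_seed)
      rt <- gated_to_realtime(
        make_gated_cine(pp, subject_id = sprintf("sub%03d", s),
                        slice_id = sprintf("sl%02d", sl)), config)
      pairs[[k]] <- prepare_pair(rt, traj, config)
      truths[[k]] <- rt
      rows[[k]] <- data.frame(subject = sprintf("sub%03d", s),
                              slice = sprintf("sl%02d", sl),
                              rr_ms = rr, n_rt_frames = dim(rt$data)[3],
                              scheme = scheme, seed = sl_seed)
    }
  }
  list(pairs = pairs, truths_rt = truths, manifest = do.call(rbind, rows))
}
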