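# Radial k-space encoding: Kaiser-Bessel gridding forward (image -> radial
# samples) and adjoint / regridding (samples -> image). Single coil, identity
# sensitivity. Grid oversampling 2x; kernel shape parameter from the Beatty
# formula beta = pi * sqrt(W^2/os^2 * (os - 0.5)^2 - 0.8). The deapodization
# is computed numerically from the same kernel (inverse DFT of the kernel
# sampled on the oversampled grid), so forward, adjoint and roll-off
# correction share one kernel definition.

kb_beta <- function(width, os = 2) {
  pi * sqrt(width^2 / os^2 * (os - 0.5)^2 - 0.8)
}

# circular shift by half the (even) side: fftshift == ifftshift for even n
fsh1 <- function(v) {
  n <- length(v)
  v[c((n / 2 + 1):n, 1:(n / 2))]
}
fsh2 <- function(m) {
  n <- nrow(m)
  i <- c((n / 2 + 1):n, 1:(n / 2))
  m[i, i, drop = FALSE]
}

# Gridding system constants for an N x N image: oversampled grid size, kernel,
# and the central-N image-domain apodization (roll-off) of the kernel.
gridding_system <- function(N, width = 8, os = 2) {
  stopifnot(N %% 2 == 0)
  G <- as.integer(round(os * N))
  beta <- kb_beta(width, os)
  u <- seq_len(G) - 1
  u <- ifelse(u > G / 2, u - G, u)
  kern <- kb_eval(abs(u), width, beta)  # kernel at integer grid offsets, DC at index 0
  # image-domain response A(r) = sum_m C(m) e^{2 pi i m r / G}: dividing the
  # image by A makes gridding match the exact DFT (A is kept unnormalized;
  # its DC value is the kernel sum)
  a_full <- Re(fsh1(stats::fft(kern, inverse = TRUE)))
  ctr <- (G / 2 - N / 2 + 1):(G / 2 + N / 2)
  list(N = N, G = G, width = width, beta = beta, apod1d = a_full[ctr])
}

# sample k (cycles/pixel) -> continuous 0-based grid index
k_to_grid <- function(k, G) k * G + G / 2

grid_positions <- function(coords, G) {
  cbind(k_to_grid(coords[, 1], G), k_to_grid(coords[, 2], G))
}

#' Radial k-space series
#'
#' Complex radial samples per frame, paired with the trajectory that generated
#' them. Samples are stored `(readout sample, spoke, frame)`.
#'
#' @param samples Complex array `(samples, spokes, frames)`.
#' @param traj The generating [make_trajectory()] object.
#' @param matrix_size Image grid side the samples refer to.
#' @param noise_sigma Optional record of an added noise level.
#' @return An object of class `kspace_series`.
#' @export
kspace_series <- function(samples, traj, matrix_size, noise_sigma = NULL) {
  stopifnot(inherits(traj, "radial_trajectory"))
  d <- dim(samples)
  stopifnot(length(d) == 3,
            d[1] == length(traj$radii),
            d[2] == ncol(traj$angles_deg),
            d[3] <= traj$n_frames)
  if (!all(is.finite(Re(samples))) || !all(is.finite(Im(samples))))
    stop("k-space samples must be finite")
  structure(list(samples = samples, traj = traj,
                 matrix_size = as.integer(matrix_size),
                 noise_sigma = noise_sigma),
            class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("k-space series: %d frames x %d spokes x %d samples (%s, matrix %d)\n",
              d[3], d[2], d[1], x$traj$scheme, x$matrix_size))
  invisible(x)
}

#' Forward radial encoding (image series to k-space samples)
#'
#' Evaluates, frame by frame, the 2D discrete Fourier transform of a square
#' image at the trajectory's non-Cartesian coordinates (type-2 NUFFT via
#' Kaiser-Bessel interpolation from a 2x-oversampled Cartesian FFT). Spatial
#' coordinates are centred on the image midpoint, so the operator approximates
#' `sum_r x(r) exp(-2 pi i k . r)` with `r` in centred pixel units. Exactly
#' linear in the image.
#'
#' @param images Real or complex array `(N, N, frames)` (a single `N x N`
#'   matrix is treated as one frame), or a [cine_volume].
#' @param traj A [make_trajectory()] trajectory with at least as many frames.
#' @param width Gridding kernel width in grid units.
#' @return A [kspace_series()].
#' @export
forward_radial <- function(images, traj, width = 8) {
  if (inherits(images, "cine_volume")) images <- images$data
  if (is.matrix(images)) images <- array(images, c(dim(images), 1))
  d <- dim(images)
  stopifnot(length(d) == 3, d[1] == d[2])
  nf <- d[3]
  if (traj$n_frames < nf)
    stop("trajectory has fewer frames than the image series")
  N <- d[1]
  gs <- gridding_system(N, width = width)
  G <- gs$G
  apod2 <- outer(gs$apod1d, gs$apod1d)
  ctr <- (G / 2 - N / 2 + 1):(G / 2 + N / 2)
  R <- length(traj$radii); ns <- ncol(traj$angles_deg)
  out <- array(complex(real = 0), c(R, ns, nf))
  for (f in seq_len(nf)) {
    img <- images[, , f] / apod2
    pad <- matrix(complex(real = 0), G, G)
    pad[ctr, ctr] <- img
    K <- fsh2(stats::fft(fsh2(pad)))
    p <- grid_positions(trajectory_coords(traj, f), G)
    v <- kb_interp(Re(K), Im(K), p, gs$width, gs$beta)
    out[, , f] <- complex(real = v$re, imaginary = v$im)
  }
  kspace_series(out, traj, N)
}

# ramp density compensation in area units (cycles/pixel)^2: each sample on a
# line occupies |k| * dk in radius and pi/spokes in angle; the DC sample gets
# the central disc of radius dk/2 split across the spokes.
radial_dcf <- function(traj) {
  dk <- 1 / length(traj$radii)
  ns <- ncol(traj$angles_deg)
  w <- abs(traj$radii) * dk * pi / ns
  w[traj$radii == 0] <- pi * (dk / 2)^2 / ns
  w
}

#' Adjoint / regridding reconstruction (k-space samples to image series)
#'
#' Grids the radial samples of each frame onto the oversampled Cartesian grid
#' with the Kaiser-Bessel kernel, inverse Fourier transforms, crops and
#' deapodizes. With `density_comp = "on"` the samples are first weighted by
#' the analytic ramp density compensation, giving the standard (aliased when
#' undersampled) gridded reconstruction; with `"off"` the operation is the
#' exact adjoint of [forward_radial()] (inner-product identity holds to
#' machine precision).
#'
#' @param ksp A [kspace_series()].
#' @param density_comp `"on"` (regridding reconstruction) or `"off"` (exact
#'   adjoint).
#' @param width Gridding kernel width in grid units (must match the forward
#'   call when used as an adjoint pair).
#' @return Complex array `(N, N, frames)`.
#' @export
adjoint_radial <- function(ksp, density_comp = c("on", "off"), width = 8) {
  stopifnot(inherits(ksp, "kspace_series"))
  density_comp <- match.arg(density_comp)
  traj <- ksp$traj
  N <- ksp$matrix_size
  gs <- gridding_system(N, width = width)
  G <- gs$G
  apod2 <- outer(gs$apod1d, gs$apod1d)
  ctr <- (G / 2 - N / 2 + 1):(G / 2 + N / 2)
  d <- dim(ksp$samples); nf <- d[3]
  w <- if (density_comp == "on") radial_dcf(traj) else NULL
  out <- array(complex(real = 0), c(N, N, nf))
  for (f in seq_len(nf)) {
    v <- ksp$samples[, , f]
    if (!is.null(w)) v <- v * w      # recycles over spokes (sample-major)
    p <- grid_positions(trajectory_coords(traj, f), G)
    g <- kb_spread(Re(v), Im(v), p, G, gs$width, gs$beta)
    grid <- complex(real = g$re, imaginary = g$im)
    dim(grid) <- c(G, G)
    img <- fsh2(stats::fft(fsh2(grid), inverse = TRUE))
    out[, , f] <- img[ctr, ctr] / apod2
  }
  out
}

#' Direct (slow) evaluation of the radial DFT
#'
#' Brute-force type-2 discrete Fourier transform: for every trajectory sample
#' `k`, `sum_r x(r) exp(-2 pi i k . r)` over centred pixel coordinates.
#' Quadratic cost; intended as an independent oracle for [forward_radial()] on
#' tiny problems.
#'
#' @inheritParams forward_radial
#' @return A [kspace_series()].
#' @export
radial_dft_direct <- function(images, traj) {
  if (inherits(images, "cine_volume")) images <- images$data
  if (is.matrix(images)) images <- array(images, c(dim(images), 1))
  d <- dim(images); N <- d[1]; nf <- d[3]
  stopifnot(d[1] == d[2], traj$n_frames >= nf)
  x <- seq_len(N) - 1 - N / 2
  R <- length(traj$radii); ns <- ncol(traj$angles_deg)
  out <- array(complex(real = 0), c(R, ns, nf))
  for (f in seq_len(nf)) {
    co <- trajectory_coords(traj, f)
    img <- images[, , f]
    # separable phase factors per sample: sum_x sum_y img e^{-2pi i kx x} e^{-2pi i ky y}
    ex <- exp(-2i * pi * outer(x, co[, 1]))   # N x nsamp
    ey <- exp(-2i * pi * outer(x, co[, 2]))
    vals <- rowSums((t(ex) %*% img) * t(ey))
    out[, , f] <- array(vals, c(R, ns))
  }
  kspace_series(out, traj, N)
}

#' Add Gaussian noise at a target image SNR
#'
#' Adds white Gaussian noise with standard deviation
#' `sigma = rms(signal) / 10^(snr_db / 20)` and clips at zero to preserve
#' magnitude-image semantics. `target_snr_db = Inf` returns the input
#' unchanged. Deterministic given `seed`.
#'
#' @param images Array or [cine_volume] of magnitude images.
#' @param target_snr_db Target SNR in dB (signal RMS over noise RMS).
#' @param seed Integer seed.
#' @return Same type as the input.
#' @export
add_image_noise <- function(images, target_snr_db, seed = 1L) {
  is_cine <- inherits(images, "cine_volume")
  x <- if (is_cine) images$data else images
  if (is.infinite(target_snr_db) && target_snr_db > 0) return(images)
  stopifnot(is.finite(target_snr_db))
  sigma <- sqrt(mean(x^2)) / 10^(target_snr_db / 20)
  set.seed(as.integer(seed))
  noisy <- pmax(x + stats::rnorm(length(x), sd = sigma), 0)
  dim(noisy) <- dim(x)
  if (is_cine) {
    images$data <- noisy
    images
  } else noisy
}
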