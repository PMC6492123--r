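# Image-quality metrics: RMSE, SSIM (Wang et al. constants), polynomial edge
# sharpness across supplied profile segments, and Bland-Altman agreement.

as_stack <- function(x) {
  if (inherits(x, "cine_volume")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  x
}

#' Root-mean-square error
#'
#' `sqrt(mean((a - b)^2))` over all voxels. Inputs are expected on a common
#' [0, 1] normalization for comparability.
#'
#' @param a,b Arrays or [cine_volume]s of identical shape.
#' @return Scalar RMSE.
#' @export
rmse <- function(a, b) {
  a <- as_stack(a); b <- as_stack(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  sqrt(mean((a - b)^2))
}

gaussian_taps <- function(sigma = 1.5, half = 5L) {
  t <- exp(-((-half):half)^2 / (2 * sigma^2))
  t / sum(t)
}

# 'valid' separable Gaussian filtering of a matrix via banded matrices
gauss_filter_valid <- function(x, taps) {
  n <- nrow(x); h <- (length(taps) - 1) / 2
  m <- n - 2 * h
  if (m < 1) stop("image smaller than the SSIM window")
  Wb <- matrix(0, m, n)
  for (i in seq_len(m)) Wb[i, i:(i + 2 * h)] <- taps
  Wb %*% x %*% t(Wb)
}

#' Structural similarity index for image series
#'
#' Per-frame SSIM with the standard constants (K1 = 0.01, K2 = 0.03, data
#' range 1) and an 11 x 11 Gaussian window with sigma = 1.5 ('valid' region),
#' averaged over frames. Symmetric in its arguments.
#'
#' @param a,b Arrays or [cine_volume]s of identical shape, normalized [0, 1].
#' @return Scalar mean SSIM in [-1, 1].
#' @export
ssim_cine <- function(a, b) {
  a <- as_stack(a); b <- as_stack(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  taps <- gaussian_taps()
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- vapply(seq_len(dim(a)[3]), function(f) {
    x <- a[, , f]; y <- b[, , f]
    mx <- gauss_filter_valid(x, taps); my <- gauss_filter_valid(y, taps)
    sxx <- gauss_filter_valid(x * x, taps) - mx^2
    syy <- gauss_filter_valid(y * y, taps) - my^2
    sxy <- gauss_filter_valid(x * y, taps) - mx * my
    mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
           ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
  }, 0)
  mean(vals)
}

bilinear_at <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r0 <- pmin(pmax(floor(r), 1), n - 1); c0 <- pmin(pmax(floor(c), 1), m - 1)
  fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(c - c0, 0), 1)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Quantitative edge sharpness from intensity profiles
#'
#' For each frame and each 2-point profile segment: sample intensities along
#' the segment by bilinear interpolation, min-max normalize the profile, fit a
#' tenth-order polynomial (on the coordinate rescaled to [-1, 1] for
#' conditioning), differentiate analytically, and take the maximum absolute
#' derivative in normalized intensity per mm. The result is the mean over
#' segments and frames. Profiles with no edge (constant within `flat_tol`) are
#' excluded with a warning. Invariant to global intensity scaling.
#'
#' @param cine Array or [cine_volume].
#' @param segments List of 2 x 2 matrices, each row an endpoint
#'   `(row, col)` in pixel coordinates.
#' @param pixel_mm Pixel spacing in mm (taken from the cine when available).
#' @param n_samples Samples per profile (>= 11 for a well-posed degree-10
#'   fit).
#' @param degree Polynomial degree.
#' @param flat_tol Relative intensity range below which a profile is treated
#'   as edge-free.
#' @return Scalar mean edge sharpness (1/mm of normalized intensity).
#' @export
edge_sharpness <- function(cine, segments, pixel_mm = NULL, n_samples = 64L,
                           degree = 10L, flat_tol = 1e-6) {
  if (inherits(cine, "cine_volume") && is.null(pixel_mm))
    pixel_mm <- cine$pixel_mm
  if (is.null(pixel_mm)) stop("pixel_mm required")
  x <- as_stack(cine)
  if (n_samples < degree + 1)
    stop(sprintf("need at least %d samples per profile for a degree-%d fit",
                 degree + 1, degree))
  if (!is.list(segments)) segments <- list(segments)
  s_unit <- seq(-1, 1, length.out = n_samples)
  dense <- seq(-1, 1, length.out = 512)
  vals <- c(); n_flat <- 0
  for (f in seq_len(dim(x)[3])) {
    img <- x[, , f]
    for (seg in segments) {
      stopifnot(is.matrix(seg), all(dim(seg) == c(2, 2)))
      rr <- seg[1, 1] + (s_unit + 1) / 2 * (seg[2, 1] - seg[1, 1])
      cc <- seg[1, 2] + (s_unit + 1) / 2 * (seg[2, 2] - seg[1, 2])
      prof <- bilinear_at(img, rr, cc)
      rng <- range(prof)
      if (diff(rng) <= flat_tol * max(abs(rng), 1)) { n_flat <- n_flat + 1; next }
      prof <- (prof - rng[1]) / diff(rng)
      cf <- pracma::polyfit(s_unit, prof, degree)
      dmax <- max(abs(pracma::polyval(pracma::polyder(cf), dense)))
      len_mm <- sqrt(sum((seg[2, ] - seg[1, ])^2)) * pixel_mm
      vals <- c(vals, dmax * 2 / len_mm)  # d/ds -> d/dmm, s spans len over 2
    }
  }
  if (n_flat > 0)
    warning(sprintf("%d constant profile(s) excluded (no edge)", n_flat))
  if (length(vals) == 0) stop("no usable profiles")
  mean(vals)
}

#' Canonical septal profile segments for the phantom
#'
#' Emits `n` short segments crossing the LV epicardial (septal-side) border
#' of the analytic phantom, for use with [edge_sharpness()]. Coordinates are
#' in the pixel frame of a prepared (cropped) cine of side `crop`; the heart
#' sits at the crop centre.
#'
#' @param params The [phantom_params()] the cine derives from.
#' @param crop Prepared image side in pixels.
#' @param crop_pixel_mm Pixel size of the prepared image in mm.
#' @param n Number of segments.
#' @param half_mm Half-length of each segment in mm.
#' @return List of 2 x 2 endpoint matrices.
#' @export
septal_segments <- function(params, crop, crop_pixel_mm, n = 6L,
                            half_mm = 6) {
  ctr <- (crop + 1) / 2
  r_mid <- params$lv_radius_mm * (1 - params$contraction_fraction / 2)
  ha <- params$heart_angle_deg * pi / 180
  angs <- ha + seq(-0.5, 0.5, length.out = n)
  lapply(angs, function(a) {
    dirv <- c(cos(a), sin(a))
    p0 <- (r_mid - half_mm) * dirv / crop_pixel_mm + ctr
    p1 <- (r_mid + half_mm) * dirv / crop_pixel_mm + ctr
    rbind(p0, p1)
  })
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are `test - ref`; bias is their mean and the limits of
#' agreement are `bias +/- 2 * sd(test - ref)`.
#'
#' @param ref_values,test_values Paired finite numeric vectors, n >= 2.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(ref_values, test_values) {
  stopifnot(length(ref_values) == length(test_values),
            all(is.finite(ref_values)), all(is.finite(test_values)))
  if (length(ref_values) < 2) stop("need at least 2 paired values")
  d <- test_values - ref_values
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 2 * s, loa_high = bias + 2 * s,
       sd = s, n = length(d))
}
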