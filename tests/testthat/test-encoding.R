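test_that("forward gridding matches the direct DFT oracle", {
  cfg <- tiny_protocol()
  traj <- make_trajectory(cfg, "tGA_rot", 1)
  set.seed(11)
  x <- array(runif(64), c(8, 8, 1))
  g <- forward_radial(x, traj)$samples
  d <- radial_dft_direct(x, traj)$samples
  expect_lt(max(Mod(g - d)) / max(Mod(d)), 1e-6)
  # delta at the centre pixel has a flat spectrum of unit magnitude
  xd <- array(0, c(8, 8, 1)); xd[5, 5, 1] <- 1
  gd <- forward_radial(xd, traj)$samples
  expect_lt(max(abs(Mod(gd) - 1)), 1e-6)
  expect_lt(max(abs(Arg(gd))), 1e-5)
})

test_that("forward operator is linear", {
  cfg <- tiny_protocol()
  traj <- make_trajectory(cfg, "REG_rot", 1)
  set.seed(12)
  x <- array(runif(64), c(8, 8, 1)); z <- array(runif(64), c(8, 8, 1))
  fa <- forward_radial(2.5 * x - 1.25 * z, traj)$samples
  fb <- 2.5 * forward_radial(x, traj)$samples -
    1.25 * forward_radial(z, traj)$samples
  expect_lt(max(Mod(fa - fb)) / max(Mod(fb)), 1e-10)
  # doubling intensity doubles sample magnitudes exactly
  expect_identical(forward_radial(2 * x, traj)$samples,
                   2 * forward_radial(x, traj)$samples)
})

test_that("adjoint passes the inner-product test for all four schemes", {
  cfg <- small_protocol()
  for (sc in c("REG_no_rot", "REG_rot", "tGA_no_rot", "tGA_rot")) {
    traj <- make_trajectory(cfg, sc, 1)
    x <- random_complex_array(c(16, 16, 1), seed = nchar(sc))
    y <- random_complex_array(c(cfg$readout_samples, 5, 1),
                              seed = nchar(sc) + 40)
    Fx <- forward_radial(x, traj)$samples
    Ahy <- adjoint_radial(kspace_series(y, traj, 16L), "off")
    lhs <- sum(Conj(Fx) * y)
    rhs <- sum(Conj(x) * Ahy)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  }
})

test_that("fully sampled gridding round trip is accurate", {
  cfg <- protocol_config(matrix_size = 64L, spokes_per_frame = 182L,
                         full_sampling_spokes = 182L, crop_size = 64L)
  traj <- make_trajectory(cfg, "REG_no_rot", 1)
  img <- phantom_frame(phantom_params(matrix = 64L, pixel_mm = 320 / 64,
                                      lv_radius_mm = 70,
                                      wall_thickness_mm = 25), 0)
  rec <- Mod(adjoint_radial(forward_radial(array(img, c(64, 64, 1)), traj),
                            "on"))[, , 1]
  nrmse <- sqrt(mean((rec - img)^2)) / diff(range(img))
  expect_lt(nrmse, 0.05)
})

test_that("gridding error decreases with kernel width", {
  cfg <- tiny_protocol()
  traj <- make_trajectory(cfg, "tGA_rot", 1)
  set.seed(13)
  x <- array(runif(64), c(8, 8, 1))
  d <- radial_dft_direct(x, traj)$samples
  errs <- vapply(c(2, 4, 6), function(w)
    max(Mod(forward_radial(x, traj, width = w)$samples - d)), 0)
  expect_true(all(diff(errs) < 0))
})

test_that("zero samples give a zero image; non-finite samples are rejected", {
  cfg <- small_protocol()
  traj <- make_trajectory(cfg, "tGA_rot", 1)
  z <- array(complex(real = 0), c(cfg$readout_samples, 5, 1))
  img <- adjoint_radial(kspace_series(z, traj, 16L), "on")
  expect_equal(max(Mod(img)), 0)
  zbad <- z; zbad[1] <- NaN
  expect_error(kspace_series(zbad, traj, 16L), "finite")
})

test_that("image-space noise injection hits the target SNR", {
  set.seed(14)
  x <- array(0.8, c(128, 128, 2))
  for (snr in c(20, 10)) {
    nz <- add_image_noise(x, snr, seed = 3)
    meas <- 10 * log10(mean(x^2) / mean((nz - x)^2))
    expect_lt(abs(meas - snr), 0.2)
    expect_true(all(nz >= 0))
  }
  expect_identical(add_image_noise(x, Inf), x)
  expect_identical(add_image_noise(x, 15, seed = 9),
                   add_image_noise(x, 15, seed = 9))
})
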