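# small instances throughout: the solver cost is quadratic in matrix size

tiny_ksp <- function(nf = 4, seed = 51, scheme = "tGA_rot") {
  cfg <- tiny_protocol()
  traj <- make_trajectory(cfg, scheme, nf)
  set.seed(seed)
  x <- array(runif(8 * 8 * nf), c(8, 8, nf))
  list(ksp = forward_radial(x, traj), x = x, cfg = cfg, traj = traj)
}

test_that("objective agrees with a brute-force oracle", {
  tk <- tiny_ksp(nf = 4)
  set.seed(52)
  x <- array(complex(real = runif(8 * 8 * 4), imaginary = runif(8 * 8 * 4)),
             c(8, 8, 4))
  cfg <- cs_config(lam = 0.37)
  got <- cs_objective(x, tk$ksp, cfg)
  # independent summation: direct DFT for the data term, explicit temporal
  # differences for the TV term
  res <- radial_dft_direct(x, tk$traj)$samples - tk$ksp$samples
  dterm <- 0.5 * sum(Mod(res)^2)
  tvterm <- 0
  for (f in 2:4) tvterm <- tvterm + sum(Mod(x[, , f] - x[, , f - 1]))
  want <- dterm + 0.37 * tvterm
  expect_lt(abs(got - want) / abs(want), 1e-6)
  # x = 0 gives half the data energy; lam = 0 drops the TV term
  expect_equal(cs_objective(x * 0, tk$ksp, cfg),
               0.5 * sum(Mod(tk$ksp$samples)^2), tolerance = 1e-10)
  expect_equal(cs_objective(x, tk$ksp, cs_config(lam = 0)), dterm,
               tolerance = 1e-6)
})

test_that("soft-thresholding solves the scalar prox problem", {
  set.seed(53)
  v <- c(stats::rnorm(20), 1i * stats::rnorm(5) + stats::rnorm(5))
  kappa <- 0.8
  got <- rtcine:::soft_complex(v, kappa)
  for (i in seq_along(v)) {
    # brute-force scalar minimizer of 0.5 |z - v|^2 + kappa |z| along the
    # direction of v (the minimizer is collinear with v)
    ts <- seq(0, Mod(v[i]) * 1.5, length.out = 4001)
    obj <- 0.5 * (ts - Mod(v[i]))^2 + kappa * ts
    tstar <- ts[which.min(obj)]
    expect_lt(abs(Mod(got[i]) - tstar), 2e-3)
    expect_lt(abs(Mod(got[i]) - max(Mod(v[i]) - kappa, 0)), 1e-12)
  }
})

test_that("objective decreases over ADMM iterations", {
  tk <- tiny_ksp(nf = 4)
  r <- cs_reconstruct(tk$ksp, cs_config(lam = 0.025, n_iters = 50))
  expect_lte(r$objective[50], r$objective[5])
  expect_lte(r$objective[50], r$objective[1])
})

test_that("lam = 0 on fully sampled static data matches gridding", {
  cfg <- protocol_config(matrix_size = 16L, spokes_per_frame = 25L,
                         full_sampling_spokes = 25L, crop_size = 16L)
  traj <- make_trajectory(cfg, "REG_no_rot", 2)
  img <- phantom_frame(phantom_params(matrix = 16L, pixel_mm = 20,
                                      lv_radius_mm = 70,
                                      wall_thickness_mm = 25), 0)
  x <- array(rep(img, 2), c(16, 16, 2))
  ksp <- forward_radial(x, traj)
  grid <- Mod(adjoint_radial(ksp, "on"))
  r <- cs_reconstruct(ksp, cs_config(lam = 0, n_iters = 10))
  nrmse <- sqrt(mean((r$recon * r$scale - grid)^2)) / diff(range(grid))
  expect_lt(nrmse, 0.05)
})

test_that("large lam forces temporal flatness", {
  tk <- tiny_ksp(nf = 4)
  r <- cs_reconstruct(tk$ksp, cs_config(lam = 20, n_iters = 30))
  expect_lt(max(Mod(rtcine:::dt_fwd(r$recon))), 1e-3)
})

test_that("temporal TV collapses alias flicker on a static scene", {
  cfg <- protocol_config(matrix_size = 32L, fov_mm = 320,
                         spokes_per_frame = 3L, full_sampling_spokes = 39L,
                         crop_size = 32L, n_frames_fixed = 4L)
  traj <- make_trajectory(cfg, "tGA_rot", 4)
  img <- phantom_frame(phantom_params(matrix = 32L, pixel_mm = 10,
                                      lv_radius_mm = 70,
                                      wall_thickness_mm = 25), 0)
  x <- array(rep(img, 4), c(32, 32, 4))
  ksp <- forward_radial(x, traj)
  aliased <- Mod(adjoint_radial(ksp, "on"))
  r <- cs_reconstruct(ksp, cs_config(lam = 0.025, n_iters = 30))
  tsd <- function(a) mean(apply(a, c(1, 2), stats::sd))
  expect_lt(tsd(r$recon), 0.1 * tsd(aliased))
})

test_that("degenerate inputs are rejected, runs are deterministic", {
  tk <- tiny_ksp(nf = 1)
  expect_error(cs_reconstruct(tk$ksp, cs_config()), "at least 2 frames")
  tk4 <- tiny_ksp(nf = 3)
  r1 <- cs_reconstruct(tk4$ksp, cs_config(lam = 0.025, n_iters = 5))
  r2 <- cs_reconstruct(tk4$ksp, cs_config(lam = 0.025, n_iters = 5))
  expect_identical(r1$recon, r2$recon)
  expect_identical(r1$objective, r2$objective)
})
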