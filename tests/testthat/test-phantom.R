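test_that("gated phantom construction, periodicity and determinism", {
  pp <- phantom_params(matrix = 80L, pixel_mm = 4, n_phases = 8L)
  g <- make_gated_cine(pp)
  expect_equal(dim(g$data), c(80, 80, 8))
  expect_true(all(g$data >= 0 & g$data <= 1))
  # full-cycle return: phase 1 reproduces phase 0
  f0 <- phantom_frame(pp, 0)
  f1 <- phantom_frame(pp, 1)
  expect_lt(sqrt(mean((f1 - f0)^2)), 1e-6)
  # determinism
  g2 <- make_gated_cine(pp)
  expect_identical(g$data, g2$data)
  # static phantom when contraction is disabled
  ps <- phantom_params(matrix = 80L, pixel_mm = 4, n_phases = 4L,
                       contraction_fraction = 1e-12)
  gs <- make_gated_cine(ps)
  for (f in 2:4) expect_lt(max(abs(gs$data[, , f] - gs$data[, , 1])), 1e-6)
  expect_error(phantom_params(matrix = 40L, pixel_mm = 1, lv_radius_mm = 24,
                              wall_thickness_mm = 9),
               "geometry exceeds")
})

test_that("gated-to-real-time conversion: frame counts and matrix", {
  cfg <- protocol_config()
  pp <- phantom_params(matrix = 240L, n_phases = 12L, rr_ms = 800)
  rt <- gated_to_realtime(make_gated_cine(pp), cfg)
  expect_equal(dim(rt$data)[3], 21)           # floor(800 / 36.4)
  expect_equal(dim(rt$data)[1:2], c(192, 192))
  pp2 <- phantom_params(matrix = 240L, n_phases = 12L, rr_ms = 1000)
  rt2 <- gated_to_realtime(make_gated_cine(pp2), cfg)
  expect_equal(dim(rt2$data)[3], 27)          # floor(1000 / 36.4)
  expect_equal(rt2$frame_ms, 36.4)
  pp3 <- phantom_params(matrix = 240L, n_phases = 4L, rr_ms = 20)
  expect_error(gated_to_realtime(make_gated_cine(pp3), cfg),
               "shorter than one real-time frame")
})

test_that("min-max normalization is idempotent and guards constants", {
  set.seed(4)
  x <- array(runif(4 * 4 * 3, 2, 7), c(4, 4, 3))
  n1 <- normalize_minmax(x)
  expect_equal(range(n1), c(0, 1))
  expect_identical(n1, normalize_minmax(n1))
  expect_identical(normalize_minmax(array(5, c(3, 3, 2))),
                   array(0, c(3, 3, 2)))
})

test_that("prepare_pair contracts: shape, normalization, endpoints", {
  b <- desk_profile()
  cfg <- b$protocol
  pp <- desk_phantom_params()
  rt <- gated_to_realtime(make_gated_cine(pp), cfg)
  nf <- dim(rt$data)[3]
  traj <- make_trajectory(cfg, "tGA_rot", nf)
  pr <- prepare_pair(rt, traj, cfg)
  expect_equal(dim(pr$truth$data), c(32, 32, 8))
  expect_equal(dim(pr$aliased$data), c(32, 32, 8))
  expect_equal(range(pr$truth$data), c(0, 1))
  expect_equal(range(pr$aliased$data), c(0, 1))
  # linear-interpolation endpoints: output frames 1 and 8 are the original
  # first and last cropped frames up to the single volume-wide min-max map
  crop <- rtcine:::crop_center(rt$data, cfg$crop_size)
  src <- c(crop[, , 1], crop[, , nf])
  out <- c(pr$truth$data[, , 1], pr$truth$data[, , 8])
  fit <- stats::lm(src ~ out)
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
  expect_gt(stats::coef(fit)[2], 0)
  # zero input maps to zero on both branches
  z <- cine_volume(array(0, dim(rt$data)), rt$pixel_mm, rt$frame_ms,
                   rr_ms = rt$rr_ms)
  prz <- prepare_pair(z, traj, cfg)
  expect_identical(max(prz$truth$data), 0)
  expect_lt(max(prz$aliased$data), 1e-12)
  expect_error(prepare_pair(rt, traj, cfg, crop_offset = c(100, 0)),
               "crop window")
})

test_that("default-protocol pairs are (20, 128, 128) volumes", {
  cfg <- protocol_config()
  pp <- phantom_params(n_phases = 10L, rr_ms = 700)
  rt <- gated_to_realtime(make_gated_cine(pp), cfg)
  traj <- make_trajectory(cfg, "tGA_rot", dim(rt$data)[3])
  pr <- prepare_pair(rt, traj, cfg)
  expect_equal(dim(pr$truth$data), c(128, 128, 20))
  expect_equal(dim(pr$aliased$data), c(128, 128, 20))
})

test_that("dataset builder: counts, manifest, reproducibility, frame bounds", {
  b <- desk_profile()
  ds <- make_dataset(2, 3, b$protocol, scheme = "tGA_rot", seed = 7,
                     phantom_matrix = b$phantom_matrix,
                     n_phases = b$n_phases, rr_range_ms = b$rr_range_ms)
  expect_length(ds$pairs, 6)
  expect_equal(nrow(ds$manifest), 6)
  ds2 <- make_dataset(2, 3, b$protocol, scheme = "tGA_rot", seed = 7,
                      phantom_matrix = b$phantom_matrix,
                      n_phases = b$n_phases, rr_range_ms = b$rr_range_ms)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$pairs[[3]]$aliased$data, ds2$pairs[[3]]$aliased$data)
  # pre-interpolation frame counts within floor bounds of rr / 36.4
  expect_true(all(ds$manifest$n_rt_frames >= floor(600 / 36.4)))
  expect_true(all(ds$manifest$n_rt_frames <= floor(1200 / 36.4)))
})

test_that("alias temporal structure follows the sampling scheme", {
  # static phantom: non-rotating schemes give frame-invariant aliases,
  # the continuously rotating tGA scheme gives frame-varying aliases
  b <- desk_profile()
  cfg <- b$protocol
  pp <- desk_phantom_params(contraction_fraction = 1e-12)
  rt <- gated_to_realtime(make_gated_cine(pp), cfg)
  st <- rt
  st$data <- array(rep(rt$data[, , 1], 6), c(dim(rt$data)[1:2], 6))
  for (sc in c("tGA_no_rot", "REG_no_rot")) {
    traj <- make_trajectory(cfg, sc, 6)
    al <- Mod(adjoint_radial(forward_radial(st$data, traj), "on"))
    expect_lt(sqrt(mean((al[, , 2] - al[, , 1])^2)), 1e-6)
  }
  traj <- make_trajectory(cfg, "tGA_rot", 6)
  al <- Mod(adjoint_radial(forward_radial(st$data, traj), "on"))
  expect_gt(sqrt(mean((al[, , 2] - al[, , 1])^2)), 1e-3)
})
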