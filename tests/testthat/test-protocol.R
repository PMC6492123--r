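test_that("tiny golden angle matches its closed form", {
  # independent evaluation of 180/(tau + 6) at 30-digit precision:
  # tau = 1.61803398874989484820..., 180 / 7.61803398874989484820
  #     = 23.6281434640248518859...
  expect_equal(tiny_golden_angle(), 23.62814346402485189, tolerance = 1e-14)
  expect_equal(round(tiny_golden_angle(), 2), 23.63)
  cfg <- protocol_config()
  expect_gt(tiny_golden_angle(), 0)
  expect_lt(tiny_golden_angle(), 2 * 180 / cfg$spokes_per_frame)
})

test_that("acceleration factor and protocol invariants", {
  expect_equal(acceleration_factor(protocol_config()), 13)
  expect_equal(acceleration_factor(
    protocol_config(spokes_per_frame = 100, full_sampling_spokes = 100)), 1)
  expect_equal(acceleration_factor(
    protocol_config(spokes_per_frame = 18, full_sampling_spokes = 182)),
    182 / 18)
  expect_equal(pixel_size_mm(protocol_config()), 320 / 192)
  expect_error(protocol_config(spokes_per_frame = 200,
                               full_sampling_spokes = 182),
               "spokes_per_frame")
  expect_error(protocol_config(crop_size = 200, matrix_size = 192),
               "crop_size")
})

test_that("REG schemes have the stated spacing and rotation", {
  cfg <- protocol_config()
  tr <- make_trajectory(cfg, "REG_no_rot", 2)
  sp <- diff(sort(tr$angles_deg[1, ]))
  expect_equal(sp, rep(180 / 14, 13))
  expect_equal(round(180 / 14, 1), 12.9)
  expect_identical(tr$angles_deg[1, ], tr$angles_deg[2, ])
  tr2 <- make_trajectory(cfg, "REG_rot", 2)
  rot <- tr2$angles_deg[2, 1] - tr2$angles_deg[1, 1]
  expect_equal(rot, (180 / 14) / 13)
  expect_equal(round(rot, 2), 0.99)
})

test_that("REG_rot tiles a fully sampled k-space in exactly 13 frames", {
  cfg <- protocol_config()
  tr <- make_trajectory(cfg, "REG_rot", 30)
  # exhaustive search over m in [1, 2 * acceleration]
  expect_identical(frames_to_full_sampling(tr), 13L)
  # 13 pooled frames are 182 uniformly spaced angles mod 180
  ang <- sort(as.vector(tr$angles_deg[1:13, ]) %% 180)
  expect_length(ang, 182)
  expect_equal(ang, (0:181) * 180 / 182, tolerance = 1e-9)
})

test_that("tGA schemes accumulate the tiny golden angle", {
  cfg <- protocol_config()
  psi <- tiny_golden_angle()
  tr <- make_trajectory(cfg, "tGA_rot", 2)
  # step between last spoke of frame 1 and first spoke of frame 2
  d <- (tr$angles_deg[2, 1] - tr$angles_deg[1, 14]) %% 360
  expect_equal(d, psi, tolerance = 1e-9)
  tr0 <- make_trajectory(cfg, "tGA_no_rot", 3)
  expect_identical(tr0$angles_deg[1, ], tr0$angles_deg[2, ])
  expect_identical(tr0$angles_deg[1, ], tr0$angles_deg[3, ])
  # within a frame, no two tGA_rot spokes coincide mod 180
  for (f in 1:2) {
    a <- sort(tr$angles_deg[f, ] %% 180)
    expect_gt(min(diff(a)), 1e-9)
  }
})

test_that("trajectory structure, coordinates and determinism", {
  cfg <- protocol_config()
  for (sc in c("REG_no_rot", "REG_rot", "tGA_no_rot", "tGA_rot")) {
    tr <- make_trajectory(cfg, sc, 3)
    expect_equal(ncol(tr$angles_deg), cfg$spokes_per_frame)
    expect_equal(nrow(tr$angles_deg), 3)
    co <- trajectory_coords(tr, 2)
    expect_true(all(sqrt(rowSums(co^2)) <= 0.5 + 1e-12))
    # samples lie on lines through the origin: cross product with the spoke
    # direction vanishes
    th <- tr$angles_deg[2, ] * pi / 180
    R <- cfg$readout_samples
    for (s in seq_along(th)) {
      seg <- co[((s - 1) * R + 1):(s * R), ]
      expect_lt(max(abs(seg[, 1] * sin(th[s]) - seg[, 2] * cos(th[s]))), 1e-12)
    }
    tr_b <- make_trajectory(cfg, sc, 3)
    expect_identical(tr$angles_deg, tr_b$angles_deg)
  }
  expect_error(make_trajectory(cfg, "spiral", 2), "unknown sampling scheme")
})
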