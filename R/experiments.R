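# Desk-scale benchmark experiments: four-scheme comparison, robustness
# sweeps (SNR / acceleration / crop shift) and the U-Net vs compressed
# sensing head-to-head, all on the analytic phantom with fixed seeds.

#' Desk-scale benchmark profile
#'
#' The package's small-problem study conditions: a reduced protocol (64
#' matrix over a heart-sized 107 mm field, 7 spokes per frame against 91
#' fully-sampling spokes so the 13x acceleration of the full protocol is
#' retained, 32-pixel crop, 8 frames after interpolation) and a reduced
#' network (2 scales, 8 base channels, 30 epochs, batches of 4). Training set
#' 40 pairs, test set 10 pairs. These sizes make a full four-network
#' comparison tractable on a single CPU core while preserving the structure
#' of the full-scale problem (same acceleration, same alias character, same
#' pipeline).
#'
#' @param train_n,test_n Training and held-out pair counts.
#' @param epochs Training epochs.
#' @return List with `protocol`, `net`, `train_n`, `test_n`, and phantom
#'   settings used by the dataset builder.
#' @export
desk_profile <- function(train_n = 40L, test_n = 10L, epochs = 30L) {
  protocol <- protocol_config(matrix_size = 64L, fov_mm = 106.88,
                              spokes_per_frame = 7L,
                              full_sampling_spokes = 91L,
                              crop_size = 32L, n_frames_fixed = 8L)
  net <- net_config(n_scales = 2L, base_channels = 8L, channel_growth = 2L,
                    loss = "l2", lr = 1e-3, batch = 4L, epochs = epochs,
                    seed = 1L)
  list(protocol = protocol, net = net, train_n = as.integer(train_n),
       test_n = as.integer(test_n), phantom_matrix = 80L, n_phases = 16L,
       rr_range_ms = c(600, 1200))
}

bench_datasets <- function(bench, scheme, seed) {
  tr <- make_dataset(bench$train_n, 1L, bench$protocol, scheme = scheme,
                     seed = seed, phantom_matrix = bench$phantom_matrix,
                     n_phases = bench$n_phases, rr_range_ms = bench$rr_range_ms)
  te <- make_dataset(bench$test_n, 1L, bench$protocol, scheme = scheme,
                     seed = seed + 10000L,
                     phantom_matrix = bench$phantom_matrix,
                     n_phases = bench$n_phases, rr_range_ms = bench$rr_range_ms)
  list(train = tr, test = te)
}

#' Evaluate reconstructions against their ground truths
#'
#' @param recons List of arrays/[cine_volume]s.
#' @param truths List of matching ground truths.
#' @param label Arm label recorded in the output.
#' @return Data frame with one row per data set: `rmse`, `ssim`.
#' @export
eval_pairs <- function(recons, truths, label = "recon") {
  stopifnot(length(recons) == length(truths))
  do.call(rbind, lapply(seq_along(recons), function(i) {
    data.frame(dataset = i, arm = label,
               rmse = rmse(recons[[i]], truths[[i]]),
               ssim = ssim_cine(recons[[i]], truths[[i]]))
  }))
}

#' Compare the four radial sampling schemes
#'
#' Trains one residual U-Net per sampling scheme on phantom data generated
#' from a shared seed (identical ground truths across schemes; only the
#' aliasing differs), evaluates each on held-out phantoms, and reports
#' per-scheme mean RMSE and SSIM for both the aliased inputs and the network
#' outputs, plus the pairwise SSIM ordering. Fully reproducible from the
#' seed.
#'
#' @param bench A [desk_profile()] (or compatible list).
#' @param seed Master seed.
#' @param schemes Character vector of schemes to include.
#' @param verbose Print progress.
#' @return List: `report` (per-scheme summary data frame), `per_dataset`
#'   (rows per test set and arm), `models` (trained networks), `manifest`.
#' @export
scheme_comparison <- function(bench = desk_profile(), seed = 1L,
                              schemes = c("REG_no_rot", "REG_rot",
                                          "tGA_no_rot", "tGA_rot"),
                              verbose = FALSE) {
  models <- list(); rows <- list(); per <- list()
  for (sc in schemes) {
    if (verbose) message("scheme ", sc)
    ds <- bench_datasets(bench, sc, seed)
    cfg <- bench$net; cfg$seed <- as.integer(seed)
    net <- build_network(cfg)
    tm <- train(net, ds$train$pairs, cfg, verbose = verbose)
    models[[sc]] <- tm
    al <- lapply(ds$test$pairs, function(p) p$aliased)
    tr <- lapply(ds$test$pairs, function(p) p$truth)
    sup <- lapply(al, function(a) suppress(tm, a))
    ev_al <- eval_pairs(al, tr, "aliased")
    ev_su <- eval_pairs(sup, tr, "suppressed")
    ev_al$scheme <- sc; ev_su$scheme <- sc
    per[[sc]] <- rbind(ev_al, ev_su)
    rows[[sc]] <- data.frame(
      scheme = sc,
      rmse_aliased = mean(ev_al$rmse), ssim_aliased = mean(ev_al$ssim),
      rmse = mean(ev_su$rmse), ssim = mean(ev_su$ssim),
      frac_improved = mean(ev_su$rmse < ev_al$rmse))
  }
  list(report = do.call(rbind, rows), per_dataset = do.call(rbind, per),
       models = models,
       manifest = list(seed = seed, schemes = schemes,
                       train_n = bench$train_n, test_n = bench$test_n,
                       epochs = bench$net$epochs))
}

#' Robustness sweeps of a trained network
#'
#' Re-evaluates a trained tGA_rot network while degrading the test inputs:
#' \describe{
#'   \item{`snr`}{Gaussian noise added to the aliased inputs at SNR levels
#'     (dB; `Inf` = no added noise).}
#'   \item{`acceleration`}{the test data re-undersampled at accelerations
#'     from 10x to 16x by varying spokes per frame (rounded with a warning
#'     when not integral), network weights fixed.}
#'   \item{`crop_shift`}{the crop window shifted over the
#'     `{0, +/-4, +/-8, +/-12}^2` offset grid (49 regions, 48 non-zero;
#'     offsets scaled down for small benchmark matrices).}
#' }
#'
#' @param kind `"snr"`, `"acceleration"` or `"crop_shift"`.
#' @param model A [train()] result for the 13x tGA_rot condition.
#' @param bench The [desk_profile()] the model was trained under.
#' @param seed Seed for the test phantoms (and the noise fields).
#' @param levels Optional override of the sweep levels.
#' @return Data frame with one row per condition: level, mean RMSE and SSIM.
#' @export
robustness_sweep <- function(kind = c("snr", "acceleration", "crop_shift"),
                             model, bench = desk_profile(), seed = 1L,
                             levels = NULL) {
  kind <- match.arg(kind)
  cfg <- bench$protocol
  te <- make_dataset(bench$test_n, 1L, cfg, scheme = "tGA_rot",
                     seed = seed + 10000L,
                     phantom_matrix = bench$phantom_matrix,
                     n_phases = bench$n_phases,
                     rr_range_ms = bench$rr_range_ms)
  truths <- lapply(te$pairs, function(p) p$truth)
  rows <- list()
  if (kind == "snr") {
    if (is.null(levels)) levels <- c(Inf, 20, 15, 10)
    for (li in seq_along(levels)) {
      snr <- levels[li]
      sup <- lapply(seq_along(te$pairs), function(i) {
        noisy <- add_image_noise(te$pairs[[i]]$aliased, snr,
                                 seed = seed + 100L * li + i)
        suppress(model, normalize_minmax(noisy))
      })
      ev <- eval_pairs(sup, truths, "suppressed")
      rows[[li]] <- data.frame(snr_db = snr, rmse = mean(ev$rmse),
                               ssim = mean(ev$ssim))
    }
  } else if (kind == "acceleration") {
    if (is.null(levels)) levels <- 10:16
    max_frames <- floor(bench$rr_range_ms[2] / cfg$frame_spacing_ms) + 1
    for (li in seq_along(levels)) {
      acc <- levels[li]
      sp <- cfg$full_sampling_spokes / acc
      if (abs(sp - round(sp)) > 1e-9)
        warning(sprintf("acceleration %gx gives %.2f spokes/frame; rounding to %d",
                        acc, sp, round(sp)), call. = FALSE)
      sp <- max(1L, as.integer(round(sp)))
      cfg_a <- cfg; cfg_a$spokes_per_frame <- sp
      traj <- make_trajectory(cfg_a, "tGA_rot", max_frames)
      sup <- list(); trs <- list()
      for (i in seq_along(te$truths_rt)) {
        pr <- prepare_pair(te$truths_rt[[i]], traj, cfg_a)
        sup[[i]] <- suppress(model, pr$aliased)
        trs[[i]] <- pr$truth
      }
      ev <- eval_pairs(sup, trs, "suppressed")
      rows[[li]] <- data.frame(acceleration = acc,
                               spokes_per_frame = sp,
                               rmse = mean(ev$rmse), ssim = mean(ev$ssim))
    }
  } else {
    if (is.null(levels)) {
      # scale the +/-12 pixel grid of the 192-matrix protocol to this matrix
      sc <- cfg$matrix_size / 192
      levels <- unique(round(c(0, 4, -4, 8, -8, 12, -12) * sc))
      levels <- sort(levels)
    }
    max_frames <- floor(bench$rr_range_ms[2] / cfg$frame_spacing_ms) + 1
    traj <- make_trajectory(cfg, "tGA_rot", max_frames)
    k <- 0
    for (ox in levels) for (oy in levels) {
      k <- k + 1
      sup <- list(); trs <- list()
      for (i in seq_along(te$truths_rt)) {
        pr <- prepare_pair(te$truths_rt[[i]], traj, cfg, crop_offset = c(ox, oy))
        sup[[i]] <- suppress(model, pr$aliased)
        trs[[i]] <- pr$truth
      }
      ev <- eval_pairs(sup, trs, "suppressed")
      rows[[k]] <- data.frame(shift_x = ox, shift_y = oy,
                              rmse = mean(ev$rmse), ssim = mean(ev$ssim))
    }
  }
  do.call(rbind, rows)
}

#' Head-to-head: deep artifact suppression vs compressed sensing
#'
#' Feeds identical undersampled k-space data to both reconstructions: the
#' gridded aliased images are passed through the trained network, and the raw
#' samples through the temporal-TV ADMM solver. Both arms (and the aliased
#' baseline) are scored against the phantom truth with RMSE, SSIM and, when
#' septal segments are available, edge sharpness. Wall-clock times are
#' recorded for information only.
#'
#' @param model A [train()] result (tGA_rot).
#' @param cs_cfg A [cs_config()].
#' @param bench The [desk_profile()] in force.
#' @param seed Seed for the test phantoms.
#' @param n_sets Number of test data sets.
#' @return List: `per_dataset` (rows per set and arm), `summary` (per-arm
#'   means), `timing` (seconds per arm).
#' @export
head_to_head <- function(model, cs_cfg = cs_config(), bench = desk_profile(),
                         seed = 1L, n_sets = 4L) {
  cfg <- bench$protocol
  te <- make_dataset(n_sets, 1L, cfg, scheme = "tGA_rot",
                     seed = seed + 20000L,
                     phantom_matrix = bench$phantom_matrix,
                     n_phases = bench$n_phases,
                     rr_range_ms = bench$rr_range_ms)
  max_frames <- floor(bench$rr_range_ms[2] / cfg$frame_spacing_ms) + 1
  traj <- make_trajectory(cfg, "tGA_rot", max_frames)
  rows <- list(); t_unet <- 0; t_cs <- 0
  segs <- septal_segments(phantom_params(matrix = bench$phantom_matrix,
                                         pixel_mm = cfg$fov_mm / bench$phantom_matrix,
                                         lv_radius_mm = 0.07 * cfg$fov_mm,
                                         wall_thickness_mm = 0.02 * cfg$fov_mm),
                          cfg$crop_size, pixel_size_mm(cfg))
  k <- 0
  for (i in seq_along(te$pairs)) {
    truth <- te$pairs[[i]]$truth
    aliased <- te$pairs[[i]]$aliased
    nf_rt <- dim(te$truths_rt[[i]]$data)[3]
    ksp <- forward_radial(te$truths_rt[[i]]$data, traj)
    ksp$samples <- ksp$samples[, , seq_len(nf_rt), drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    un <- suppress(model, aliased)
    t_unet <- t_unet + proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    cs <- cs_reconstruct(ksp, cs_cfg)
    t_cs <- t_cs + proc.time()[["elapsed"]] - t0
    # bring the CS volume through the same crop/interp/normalize pipeline
    cs_prep <- normalize_minmax(interp_time(
      crop_center(cs$recon, cfg$crop_size),
      seq_len(nf_rt) - 1,
      seq(0, nf_rt - 1, length.out = cfg$n_frames_fixed)))
    es <- function(x) tryCatch(
      suppressWarnings(edge_sharpness(x, segs, pixel_mm = pixel_size_mm(cfg))),
      error = function(e) NA_real_)
    for (arm in c("truth", "aliased", "unet", "cs")) {
      rec <- switch(arm, truth = truth, aliased = aliased, unet = un,
                    cs = cs_prep)
      k <- k + 1
      rows[[k]] <- data.frame(
        dataset = i, arm = arm,
        rmse = rmse(rec, truth), ssim = ssim_cine(rec, truth),
        edge_sharpness = es(rec),
        cs_objective_final = if (arm == "cs")
          cs$objective[length(cs$objective)] else NA_real_)
    }
  }
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per, per$arm), function(d)
    data.frame(arm = d$arm[1], rmse = mean(d$rmse), ssim = mean(d$ssim),
               edge_sharpness = mean(d$edge_sharpness, na.rm = TRUE))))
  list(per_dataset = per, summary = summ,
       timing = c(unet_s = t_unet, cs_s = t_cs))
}
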