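# rtcine — deep artifact suppression for radial real-time cardiac cine MR

Real-time cardiac cine imaging needs high undersampling: at 14 radial spokes
per frame against the 182 uniformly spaced spokes that fully sample a
192 × 192 k-space, every frame is acquired at 13× acceleration and the
gridded reconstruction is dominated by aliasing. `rtcine` is a simulation
and reconstruction toolkit for this regime. It provides:

- **Radial trajectories** — regular and tiny-golden-angle spoke spacing,
  each with and without inter-frame rotation (`REG_no_rot`, `REG_rot`,
  `tGA_no_rot`, `tGA_rot`). The tiny golden angle is
  ψ = 180°/(τ + 6) ≈ 23.63° with τ the golden ratio; continuously rotating
  by ψ across frames (`tGA_rot`) makes the aliases incoherent in space and
  time, which is what turns de-aliasing into a denoising problem.
- **Gridding operators** — Kaiser–Bessel type-2 NUFFT forward and exact
  adjoint / density-compensated regridding, the machinery that simulates
  undersampled acquisitions and drives the iterative solver.
- **A synthetic cardiac phantom pipeline** — an analytic contracting
  short-axis phantom with bSSFP-like contrast standing in for a gated
  breath-hold cine library, converted to synthetic real-time frames
  (36.4 ms spacing, frame count = ⌊RR/36.4⌋) and paired
  (ground-truth, aliased) training volumes cropped to 128 × 128 × 20 and
  normalized to [0, 1].
- **Deep artifact suppression** — a 3D (2D + time) residual U-Net,
  `output = ReLU(input + residual)`, isotropic 3 × 3 × 3 kernels, trained
  with ADAM on the l2 (optionally l1) loss. The convolution kernels,
  backpropagation and optimizer are implemented in the package (im2col +
  BLAS GEMM, finite-difference-verified gradients).
- **A compressed-sensing comparator** — GRASP-style temporal
  total-variation reconstruction, `argmin_x ½‖Ax − y‖² + λ‖D_t x‖₁`,
  solved by ADMM (CG x-update, soft-threshold z-update, 50 iterations,
  λ = 0.025 on a normalized scale).
- **Evaluation** — RMSE, SSIM, tenth-order-polynomial edge sharpness,
  Bland–Altman bias and limits of agreement, scheme-comparison benchmark
  and robustness sweeps (SNR, acceleration, crop shift).

## Worked example

Train a small network on synthetic phantom pairs and evaluate on held-out
phantoms (desk-scale profile: 64-matrix protocol at the same 13×
acceleration, 32 × 32 × 8 prepared volumes):

```r
library(rtcine)

cfg <- protocol_config()
round(tiny_golden_angle(), 2)   # 23.63
acceleration_factor(cfg)        # 13

b <- desk_profile(train_n = 16L, test_n = 3L, epochs = 20L)
ds <- make_dataset(16, 1, b$protocol, scheme = "tGA_rot", seed = 1,
                   phantom_matrix = b$phantom_matrix, n_phases = b$n_phases,
                   rr_range_ms = b$rr_range_ms)
cfgn <- b$net; cfgn$epochs <- 20L
tm <- train(build_network(cfgn), ds$pairs, cfgn)
#> Trained residual U-Net: 16 pairs, 20 epochs, final l2 loss 0.01513

te <- make_dataset(3, 1, b$protocol, scheme = "tGA_rot", seed = 2,
                   phantom_matrix = b$phantom_matrix, n_phases = b$n_phases,
                   rr_range_ms = b$rr_range_ms)
al  <- lapply(te$pairs, `[[`, "aliased")
tr  <- lapply(te$pairs, `[[`, "truth")
sup <- lapply(al, function(a) suppress(tm, a))
rbind(eval_pairs(al, tr, "aliased"), eval_pairs(sup, tr, "suppressed"))
#>   dataset        arm      rmse      ssim
#> 1       1    aliased 0.1374288 0.5043107
#> 2       2    aliased 0.2203733 0.4379062
#> 3       3    aliased 0.1601592 0.4792313
#> 4       1 suppressed 0.1453936 0.5104923
#> 5       2 suppressed 0.1078315 0.5289288
#> 6       3 suppressed 0.1003696 0.5244059
```

RMSE/SSIM are measured against the phantom ground truth; lower RMSE and
higher SSIM are better. Even this abbreviated training run removes most of
the aliasing energy on two of the three held-out phantoms and raises SSIM
on all three; the full shipped benchmark (`scheme_comparison()`, 40
training pairs, 30 epochs, four schemes) improves every held-out case and
reproduces the expected ordering — continuously rotating tiny-golden-angle
sampling reconstructs best. `head_to_head()` runs the same k-space through
the network and the temporal-TV solver and scores both arms, and
`robustness_sweep()` degrades the inputs (added noise, different
accelerations, shifted crops) against a fixed trained network.

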