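# Shared small fixtures, built in code.

# tiny protocol for operator tests (8x8 image, 3 spokes)
tiny_protocol <- function(readout = 16L) {
  protocol_config(matrix_size = 8L, fov_mm = 320, spokes_per_frame = 3L,
                  full_sampling_spokes = 13L, crop_size = 8L,
                  n_frames_fixed = 4L, readout_samples = readout)
}

small_protocol <- function() {
  protocol_config(matrix_size = 16L, fov_mm = 320, spokes_per_frame = 5L,
                  full_sampling_spokes = 25L, crop_size = 16L,
                  n_frames_fixed = 4L)
}

desk_phantom_params <- function(...) {
  b <- desk_profile()
  phantom_params(matrix = b$phantom_matrix,
                 pixel_mm = b$protocol$fov_mm / b$phantom_matrix,
                 rr_ms = 800, n_phases = b$n_phases, ...)
}

random_complex_array <- function(dims, seed = 1) {
  set.seed(seed)
  array(complex(real = stats::rnorm(prod(dims)),
                imaginary = stats::rnorm(prod(dims))), dims)
}

# memoised desk-scale benchmark results shared between the heavy
# scheme-comparison and robustness blocks
.bench_cache <- new.env(parent = emptyenv())

bench_comparison <- function(seed = 1L) {
  key <- paste0("sc_", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- scheme_comparison(desk_profile(), seed = seed)
  .bench_cache[[key]]
}
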