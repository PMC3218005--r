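# shared fixture builders for the test suite

# noise-free quadratic series in the monitor's default per-frame units
quadratic_series <- function(n_frames = 400L, a2 = 1e-6, a1 = 1e-4,
                             c0 = 0.05, noise_sigma = 0, seed = 1L) {
  generate_growth_series(synthetic_growth_params(
    "quadratic", coefficients = c(a2 = a2, a1 = a1), c0 = c0,
    n_frames = n_frames, noise_sigma = noise_sigma, seed = seed))
}

# quarter-scale synthetic frame targeting a nominal coverage fraction
coverage_image_params <- function(coverage, seed, ...) {
  mean_r <- mean(c(8, 20))
  n <- round(coverage * 348 * 260 / (pi * mean_r^2))
  synthetic_image_params(n_cells = n, seed = seed, ...)
}

# segmentation settings matched to the quarter-scale fixture geometry
quarter_scale_seg <- function(...) {
  segmentation_params(dilation_radius_px = 2, ...)
}

# small fast dataset settings for pipeline tests
small_image_params <- function(seed = 1L, ...) {
  synthetic_image_params(width_px = 116L, height_px = 87L,
                         cell_radius_px = c(4, 8), noise_sigma = 0.005,
                         seed = seed, ...)
}

small_seg <- function() {
  segmentation_params(background_kernel_px = 20, dilation_radius_px = 1)
}

small_config <- function(min_frames = 20L, ...) {
  monitor_config(window_frames = 60L, min_frames = min_frames,
                 horizon_min = 60, var_window = 12L,
                 fovs_per_timepoint = 3L, ...)
}
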