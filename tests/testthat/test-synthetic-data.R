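test_that("image generation is deterministic for a fixed seed", {
  p <- synthetic_image_params(n_cells = 15, seed = 11)
  a <- generate_cell_image(p)
  b <- generate_cell_image(p)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$mask$labels, b$mask$labels)
  # a different seed changes the image
  c <- generate_cell_image(synthetic_image_params(n_cells = 15, seed = 12))
  expect_false(identical(a$mask$labels, c$mask$labels))
})

test_that("zero cells give a background-only frame and an empty mask", {
  p <- synthetic_image_params(n_cells = 0, shade_off_amplitude = 0, seed = 2)
  out <- generate_cell_image(p)
  expect_equal(compute_confluency(out$mask), 0)
  # background plus noise only: pixels scatter tightly around the background
  expect_lt(max(abs(out$frame$pixels - 0.5)), 6 * p$noise_sigma)
})

test_that("truth-mask confluency is the exact set-pixel fraction", {
  out <- generate_cell_image(synthetic_image_params(n_cells = 8, seed = 5))
  m <- out$mask$labels
  expect_identical(compute_confluency(out$mask), sum(m == 1) / length(m))
})

test_that("placement targeting ~25% coverage lands in [0.20, 0.30]", {
  # n_cells * mean cell area ~ 0.25 * frame area, rejection keeps overlap low
  for (seed in c(1, 2, 3)) {
    p <- coverage_image_params(0.25, seed = seed, max_overlap_frac = 0.15)
    out <- generate_cell_image(p)
    expect_gte(compute_confluency(out$mask), 0.20)
    expect_lte(compute_confluency(out$mask), 0.30)
  }
})

test_that("invalid image parameters are rejected", {
  expect_error(synthetic_image_params(width_px = 0), "positive")
  expect_error(synthetic_image_params(n_cells = -1), "non-negative")
  expect_error(synthetic_image_params(noise_sigma = -0.1), "non-negative")
})

test_that("zero-noise growth series equals the closed-form family", {
  k <- 0:199
  s <- quadratic_series(n_frames = 200)
  expect_equal(s$value, 1e-6 * k^2 + 1e-4 * k + 0.05, tolerance = 0)
  expect_equal(s$frame, k)
  expect_equal(s$time_min, k * 5)
})

test_that("zero-noise logistic series is strictly non-decreasing", {
  p <- synthetic_growth_params("logistic", capacity = 0.9, rate = 0.02,
                               c0 = 0.05, n_frames = 500)
  s <- generate_growth_series(p)
  expect_true(all(diff(s$value) >= 0))
  expect_lt(max(s$value), 0.9 + 1e-12)
})

test_that("noisy series is unbiased around the clean value (LLN)", {
  # constant clean value 0.3: a2 = a1 = 0
  s <- generate_growth_series(synthetic_growth_params(
    "quadratic", coefficients = c(0, 0), c0 = 0.3, n_frames = 1000,
    noise_sigma = 0.005, seed = 99))
  expect_lt(abs(mean(s$value) - 0.3), 3 * 0.005 / sqrt(1000))
})

test_that("growth series generation is seed-deterministic and validates", {
  p <- synthetic_growth_params(n_frames = 50, noise_sigma = 0.01, seed = 4)
  expect_identical(generate_growth_series(p)$value,
                   generate_growth_series(p)$value)
  expect_error(synthetic_growth_params(noise_sigma = -1), "non-negative")
  expect_error(synthetic_growth_params(n_frames = 0), ">= 1")
})

test_that("timelapse dataset writes the expected files and truth table", {
  dir <- withr::local_tempdir()
  growth <- synthetic_growth_params("quadratic", coefficients = c(0, 0.05),
                                    c0 = 0.1, n_frames = 3, seed = 2)
  img <- small_image_params(seed = 3)
  man <- generate_timelapse_dataset(growth, img, n_fovs = 12, out_dir = dir)
  files <- list.files(dir, pattern = "^frame_.*\\.png$", recursive = TRUE)
  expect_length(files, 36)
  expect_length(unlist(man$frames, recursive = FALSE), 36)

  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_setequal(names(truth), c("frame", "fov", "true_confluency"))
  avg <- tapply(truth$true_confluency, truth$frame, mean)
  expect_true(all(diff(avg) >= 0))  # monotone growth => monotone coverage

  # per-FOV coverage never decreases (cells are only added)
  for (f in unique(truth$fov)) {
    tf <- truth[truth$fov == f, ]
    expect_true(all(diff(tf$true_confluency[order(tf$frame)]) >= 0))
  }

  dir2 <- withr::local_tempdir()
  generate_timelapse_dataset(growth, img, n_fovs = 12, out_dir = dir2)
  expect_identical(readLines(file.path(dir, "truth.csv")),
                   readLines(file.path(dir2, "truth.csv")))
})

test_that("dataset images round-trip through the frame reader", {
  dir <- withr::local_tempdir()
  growth <- synthetic_growth_params("quadratic", coefficients = c(0, 0),
                                    c0 = 0.2, n_frames = 1, seed = 7)
  generate_timelapse_dataset(growth, small_image_params(seed = 8),
                             n_fovs = 1, out_dir = dir, format = "tiff")
  f <- list.files(dir, pattern = "\\.tif$", recursive = TRUE, full.names = TRUE)
  fr <- read_frame(f[1])
  expect_equal(dim(fr$pixels), c(87, 116))
  expect_true(all(fr$pixels >= 0 & fr$pixels <= 1))
})
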