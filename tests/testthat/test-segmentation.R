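two_level_fixture <- function(seed = 3, n_cells = 20) {
  generate_cell_image(synthetic_image_params(
    n_cells = n_cells, halo_amplitude = 0, shade_off_amplitude = 0,
    noise_sigma = 0, seed = seed))
}

test_that("restoration flattens a constant frame to zero", {
  px <- matrix(0.5, 60, 80)
  expect_true(all(restore_image(px) == 0))
  expect_true(all(restore_image(px, segmentation_params(restoration = "none")) == 0))
})

test_that("restoration is positive exactly on cell bodies for clean two-level frames", {
  out <- two_level_fixture()
  r <- restore_image(out$frame)
  expect_true(all(r[out$mask$labels == 1] > 0))
  expect_true(all(r[out$mask$labels == 0] == 0))
})

test_that("shade-off without cells leaves only a small residual", {
  p <- synthetic_image_params(n_cells = 0, halo_amplitude = 0,
                              noise_sigma = 0, shade_off_amplitude = 0.08,
                              seed = 9)
  out <- generate_cell_image(p)
  expect_lt(max(restore_image(out$frame)), 0.05)
})

test_that("unknown restoration plugins error; registered ones run", {
  px <- matrix(0.5, 20, 20)
  expect_error(restore_image(px, segmentation_params(restoration = "nope")),
               "unknown restoration plugin")
  register_restoration("flat0", function(pixels, params) pixels * 0)
  r <- restore_image(px, segmentation_params(restoration = "flat0"))
  expect_true(all(r == 0))
})

test_that("thresholding guards degenerate dynamic range and splits two levels exactly", {
  expect_equal(compute_confluency(threshold_mask(matrix(0, 50, 50))), 0)
  r <- matrix(0, 40, 40); r[10:20, 5:15] <- 0.8
  m <- threshold_mask(r)
  expect_identical(m$labels, (r > 0) * 1)
})

test_that("full pipeline reproduces truth masks pixel-exactly on artifact-free frames", {
  for (seed in c(3, 17)) {
    out <- two_level_fixture(seed)
    seg <- segment_frame(out$frame, segmentation_params(dilation_radius_px = 0))
    expect_identical(seg$mask$labels, out$mask$labels)
  }
})

test_that("pre-dilation confluency tracks nominal ~25% coverage", {
  out <- generate_cell_image(coverage_image_params(0.25, seed = 21,
                                                   max_overlap_frac = 0.15))
  seg <- segment_frame(out$frame, quarter_scale_seg())
  pre <- compute_confluency(seg$pre_dilation)
  expect_gte(pre, 0.15)
  expect_lte(pre, 0.30)
})

test_that("dilation: identity at radius 0, disk area for a point, superset always", {
  m <- matrix(0, 31, 31); m[16, 16] <- 1
  expect_identical(dilate_mask(m, 0)$labels, m)
  # disk pixel count under the production structuring-element constructor
  expect_equal(sum(dilate_mask(m, 8)$labels),
               sum(EBImage::makeBrush(17, "disc")))
  out <- generate_cell_image(synthetic_image_params(n_cells = 10, seed = 6))
  d <- dilate_mask(out$mask, 3)
  expect_true(all(d$labels >= out$mask$labels))
  expect_error(dilate_mask(m, -1), ">= 0")
})

test_that("confluency is monotone non-decreasing in dilation radius", {
  out <- generate_cell_image(synthetic_image_params(n_cells = 12, seed = 8))
  cf <- vapply(c(0, 1, 2, 4, 8),
               function(r) compute_confluency(dilate_mask(out$mask, r)),
               numeric(1))
  expect_true(all(diff(cf) >= 0))
})

test_that("compute_confluency is the exact pixel ratio", {
  expect_equal(compute_confluency(matrix(0, 100, 100)), 0)
  expect_equal(compute_confluency(matrix(1, 50, 60)), 1)
  m <- matrix(0, 1040, 1392)
  m[seq_len(723840)] <- 1
  expect_equal(compute_confluency(m), 0.5)
  expect_error(compute_confluency(matrix(numeric(0), 0, 0)), "empty")
})

test_that("average_confluency matches an independent accumulation", {
  expect_equal(average_confluency(rep(0.5, 12)), 0.5)
  expect_equal(average_confluency(c(0.4, 0.6)), 0.5)
  set.seed(1)
  v <- runif(37)
  acc <- 0
  for (x in v) acc <- acc + x
  expect_equal(average_confluency(v), acc / length(v), tolerance = 1e-12)
  expect_error(average_confluency(numeric(0)), "no confluency")
  expect_error(average_confluency(c(0.5, 1.2)), "in \\[0, 1\\]")
})

test_that("pipeline output is invariant to a constant intensity offset", {
  out <- two_level_fixture(seed = 13)
  px <- out$frame$pixels
  base <- segment_frame(px, segmentation_params(dilation_radius_px = 0))
  shifted <- segment_frame(px + 0.07, segmentation_params(dilation_radius_px = 0))
  expect_identical(base$mask$labels, shifted$mask$labels)
})

test_that("overlay tints the green channel exactly on mask pixels", {
  out <- two_level_fixture(seed = 4, n_cells = 6)
  px <- out$frame$pixels
  empty <- render_overlay(px, matrix(0, nrow(px), ncol(px)))
  expect_equal(empty[, , 1], px)
  expect_equal(empty[, , 2], px)
  expect_equal(empty[, , 3], px)
  full <- render_overlay(px, matrix(1, nrow(px), ncol(px)))
  expect_true(all(full[, , 2] > full[, , 1]))
  ov <- render_overlay(px, out$mask)
  on <- out$mask$labels == 1
  expect_true(all((ov[, , 2] > ov[, , 1]) == on))
  expect_error(render_overlay(px, matrix(0, 2, 2)), "mismatch")
})

test_that("masks survive a PNG round trip", {
  dir <- withr::local_tempdir()
  out <- two_level_fixture(seed = 5, n_cells = 8)
  path <- file.path(dir, "mask.png")
  write_mask(out$mask, path)
  back <- read_mask(path, provenance = "human")
  expect_identical(back$labels, out$mask$labels)
})
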