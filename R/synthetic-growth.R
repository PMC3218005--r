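#' Parameters for synthetic confluency growth curves
#'
#' Two clean families are supported. `"quadratic"` evaluates
#' `a2*k^2 + a1*k + c0` at frame `k` (per-frame units), the model class the
#' monitoring pipeline itself fits. `"logistic"` evaluates
#' `K / (1 + ((K - c0)/c0) * exp(-r*k))`, a saturating curve with carrying
#' capacity `K` and per-frame rate `r`. Gaussian noise is added per frame
#' and the result clipped to `[0, 1]`.
#'
#' @param family `"quadratic"` or `"logistic"`.
#' @param coefficients for the quadratic family, `c(a2, a1)` in per-frame
#'   units (the constant term is `c0`). Ignored for logistic.
#' @param capacity,rate logistic carrying capacity `K` in `(0, 1]` and
#'   per-frame growth rate `r > 0`. Ignored for quadratic.
#' @param c0 initial confluency in `[0, 1]` (frame 0 clean value).
#' @param frame_interval_min minutes between frames (default 5).
#' @param n_frames number of frames to generate.
#' @param noise_sigma standard deviation of the additive noise, confluency
#'   units; 0 returns the clean curve.
#' @param seed integer seed.
#' @return A parameter list of class `synthetic_growth_params`.
#' @export
synthetic_growth_params <- function(family = c("quadratic", "logistic"),
                                    coefficients = c(a2 = 1e-6, a1 = 1e-4),
                                    capacity = 0.95, rate = 0.01,
                                    c0 = 0.05, frame_interval_min = 5,
                                    n_frames = 600L, noise_sigma = 0,
                                    seed = 1L) {
  family <- match.arg(family)
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (c0 < 0 || c0 > 1) stop("c0 must be in [0, 1]")
  if (family == "logistic") {
    if (capacity <= 0 || capacity > 1) stop("capacity must be in (0, 1]")
    if (rate <= 0) stop("rate must be positive")
    if (c0 <= 0) stop("logistic growth needs c0 > 0")
  }
  structure(
    list(family = family, coefficients = coefficients, capacity = capacity,
         rate = rate, c0 = c0, frame_interval_min = frame_interval_min,
         n_frames = as.integer(n_frames), noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "synthetic_growth_params")
}

# clean family value at 0-based frame index k (vectorised)
clean_growth_value <- function(p, k) {
  if (p$family == "quadratic") {
    a2 <- p$coefficients[[1]]; a1 <- p$coefficients[[2]]
    a2 * k^2 + a1 * k + p$c0
  } else {
    K <- p$capacity
    K / (1 + ((K - p$c0) / p$c0) * exp(-p$rate * k))
  }
}

#' Generate a confluency growth time series
#'
#' @param params a [synthetic_growth_params()] object.
#' @return A [confluency_series] of length `n_frames` (frames `0 ..
#'   n_frames-1`); each value is the clean family value plus
#'   `N(0, noise_sigma)`, clipped to `[0, 1]`.
#' @examples
#' s <- generate_growth_series(synthetic_growth_params(n_frames = 100))
#' head(s)
#' @export
generate_growth_series <- function(params) {
  stopifnot(inherits(params, "synthetic_growth_params"))
  p <- params
  k <- seq_len(p$n_frames) - 1L
  clean <- clip01(clean_growth_value(p, k))
  vals <- if (p$noise_sigma > 0)
    with_seed(p$seed, clip01(clean + stats::rnorm(p$n_frames, 0, p$noise_sigma)))
  else clean
  confluency_series(k, vals, p$frame_interval_min)
}

#' Write a synthetic time-lapse image dataset to disk
#'
#' Emulates a multi-dish acquisition: `n_fovs` fields of view (grouped three
#' per dish, as on the source instrument) are imaged at every frame of the
#' growth series. Per field of view, a seeded pool of cells is laid down
#' once and cells are revealed cumulatively so that the true covered
#' fraction tracks the (clean) growth series; coverage therefore never
#' decreases when the series is monotone. Images go to
#' `out_dir/<dish>/<fov>/frame_<k>.<ext>` alongside `manifest.json`
#' (frame -> files) and `truth.csv` (`frame,fov,true_confluency`).
#'
#' @param growth a [synthetic_growth_params()] object driving coverage.
#' @param image a [synthetic_image_params()] object; `n_cells` is ignored
#'   (coverage is driven by the series) and `seed` seeds the per-FOV pools.
#' @param n_fovs number of fields of view per time point.
#' @param out_dir output directory (created if needed).
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit) image container.
#' @return The manifest, invisibly: a list with `frames`, `fovs`, paths.
#' @export
generate_timelapse_dataset <- function(growth, image, n_fovs = 12L,
                                       out_dir, format = c("png", "tiff")) {
  stopifnot(inherits(growth, "synthetic_growth_params"),
            inherits(image, "synthetic_image_params"))
  format <- match.arg(format)
  if (n_fovs < 1) stop("n_fovs must be >= 1")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  series <- generate_growth_series(
    synthetic_growth_params(growth$family, growth$coefficients,
                            growth$capacity, growth$rate, growth$c0,
                            growth$frame_interval_min, growth$n_frames,
                            noise_sigma = 0, seed = growth$seed))
  target <- series$value
  ext <- if (format == "png") "png" else "tif"
  n_frames <- growth$n_frames
  fov_ids <- sprintf("fov_%02d", seq_len(n_fovs))
  dish_ids <- sprintf("dish_%d", (seq_len(n_fovs) - 1L) %/% 3L + 1L)
  truth <- vector("list", n_fovs)
  frames <- lapply(seq_len(n_frames), function(i) list())

  for (f in seq_len(n_fovs)) {
    fov_seed <- (image$seed + 7919L * f) %% .Machine$integer.max
    pool <- fov_cell_pool(image, max(target), fov_seed)
    # number of pool cells needed per frame to first reach each target
    m_per_frame <- findInterval(target - 1e-12, pool$cum_cov) + 1L
    m_per_frame <- pmin(m_per_frame, length(pool$cells))
    if (target[1] <= 0) m_per_frame[target <= 0] <- 0L
    dir.create(file.path(out_dir, dish_ids[f], fov_ids[f]),
               showWarnings = FALSE, recursive = TRUE)
    rows <- data.frame(frame = series$frame, fov = fov_ids[f],
                       true_confluency = c(0, pool$cum_cov)[m_per_frame + 1L])
    truth[[f]] <- rows
    for (i in seq_len(n_frames)) {
      m <- m_per_frame[i]
      img <- render_pool_image(pool, m, image,
                               noise_seed = (fov_seed + i) %% .Machine$integer.max)
      rel <- file.path(dish_ids[f], fov_ids[f],
                       sprintf("frame_%05d.%s", series$frame[i], ext))
      write_frame(img, file.path(out_dir, rel), format)
      frames[[i]][[fov_ids[f]]] <- rel
    }
  }

  truth_df <- do.call(rbind, truth)
  truth_df <- truth_df[order(truth_df$frame, truth_df$fov), ]
  utils::write.csv(truth_df, file.path(out_dir, "truth.csv"), row.names = FALSE)
  manifest <- list(
    n_frames = n_frames, n_fovs = n_fovs,
    frame_interval_min = growth$frame_interval_min,
    format = format,
    fovs = stats::setNames(as.list(dish_ids), fov_ids),
    frames = stats::setNames(frames, sprintf("%d", series$frame)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# seeded pool of cells for one FOV, with cumulative union coverage
fov_cell_pool <- function(image, max_cov, seed) {
  p <- image
  with_seed(seed, {
    cells <- list(); fps <- list(); cum <- numeric(0)
    cover <- matrix(FALSE, p$height_px, p$width_px)
    total <- length(cover)
    while ((length(cum) == 0 || cum[length(cum)] < min(1, max_cov + 0.02)) &&
           length(cells) < 5000L) {
      cell <- draw_cell(p)
      fp <- cell_footprint(cell, p)
      cover[fp$rows, fp$cols] <- cover[fp$rows, fp$cols] | fp$body
      cells[[length(cells) + 1L]] <- cell
      fps[[length(fps) + 1L]] <- fp
      cum <- c(cum, sum(cover) / total)
    }
    list(cells = cells, fps = fps, cum_cov = cum,
         height = p$height_px, width = p$width_px)
  })
}

# render the first m pool cells as a frame matrix
render_pool_image <- function(pool, m, p, noise_seed) {
  body_mask <- matrix(FALSE, pool$height, pool$width)
  halo_acc  <- matrix(0, pool$height, pool$width)
  if (m > 0) for (j in seq_len(m)) {
    fp <- pool$fps[[j]]
    body_mask[fp$rows, fp$cols] <- body_mask[fp$rows, fp$cols] | fp$body
    halo_acc[fp$rows, fp$cols] <- pmax(halo_acc[fp$rows, fp$cols], fp$halo)
  }
  halo_acc[body_mask] <- 0
  with_seed(noise_seed, {
    shade <- if (p$shade_off_amplitude > 0)
      p$shade_off_amplitude * shade_off_field(p)
    else 0
    img <- p$background_level + p$body_contrast * body_mask +
      p$halo_amplitude * halo_acc + shade
    if (p$noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, p$noise_sigma)
    clip01(img)
  })
}
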