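#' Parameters for the synthetic phase-contrast image generator
#'
#' The generator renders the two artifacts that make phase-contrast
#' segmentation non-trivial: a bright halo ring around each dark cell body,
#' and a smooth shade-off intensity gradient across the frame. Defaults are
#' quarter-scale relative to a 1392x1040 px instrument frame to keep
#' simulations fast; pass `width_px = 1392, height_px = 1040` (and scale
#' `cell_radius_px` by 4) for full-scale frames.
#'
#' @param width_px,height_px frame size in pixels.
#' @param n_cells number of cells to place (possibly overlapping ellipses).
#' @param cell_radius_px length-2 range of ellipse semi-axes, pixels.
#' @param background_level background intensity in `[0, 1]`.
#' @param body_contrast signed intensity offset of the cell body
#'   (negative = dark body, the phase-contrast appearance).
#' @param halo_amplitude peak intensity of the bright halo ring just outside
#'   the body boundary; 0 disables halos.
#' @param halo_width_px Gaussian radial width of the halo ring, pixels.
#' @param shade_off_amplitude maximum absolute intensity of the smooth
#'   low-order polynomial shade-off field; 0 disables it.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param max_overlap_frac maximum fraction of a candidate cell's area that
#'   may already be covered before the placement is rejected and redrawn
#'   (1 = overlaps always accepted).
#' @param seed integer seed; the same parameters and seed reproduce the
#'   image and mask bit for bit.
#' @return A validated parameter list of class `synthetic_image_params`.
#' @seealso [generate_cell_image()]
#' @export
synthetic_image_params <- function(width_px = 348L, height_px = 260L,
                                   n_cells = 40L,
                                   cell_radius_px = c(8, 20),
                                   background_level = 0.5,
                                   body_contrast = -0.25,
                                   halo_amplitude = 0.15,
                                   halo_width_px = 3,
                                   shade_off_amplitude = 0.08,
                                   noise_sigma = 0.01,
                                   max_overlap_frac = 1,
                                   seed = 1L) {
  if (width_px < 1 || height_px < 1) stop("frame dimensions must be positive")
  if (n_cells < 0) stop("n_cells must be non-negative")
  if (length(cell_radius_px) != 2 || any(cell_radius_px <= 0) ||
      cell_radius_px[1] > cell_radius_px[2])
    stop("cell_radius_px must be a positive (min, max) range")
  if (background_level < 0 || background_level > 1)
    stop("background_level must be in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (halo_width_px <= 0) stop("halo_width_px must be positive")
  if (max_overlap_frac < 0 || max_overlap_frac > 1)
    stop("max_overlap_frac must be in [0, 1]")
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         n_cells = as.integer(n_cells), cell_radius_px = cell_radius_px,
         background_level = background_level, body_contrast = body_contrast,
         halo_amplitude = halo_amplitude, halo_width_px = halo_width_px,
         shade_off_amplitude = shade_off_amplitude, noise_sigma = noise_sigma,
         max_overlap_frac = max_overlap_frac, seed = as.integer(seed)),
    class = "synthetic_image_params")
}

# draw one random ellipse spec within the frame
draw_cell <- function(p) {
  list(cx = stats::runif(1, 1, p$width_px),
       cy = stats::runif(1, 1, p$height_px),
       a  = stats::runif(1, p$cell_radius_px[1], p$cell_radius_px[2]),
       b  = stats::runif(1, p$cell_radius_px[1], p$cell_radius_px[2]),
       theta = stats::runif(1, 0, pi))
}

# body / halo contribution of one cell over its bounding box.
# rho is the elliptical radial coordinate: rho <= 1 inside the body.
cell_footprint <- function(cell, p) {
  r_max <- max(cell$a, cell$b) + 4 * p$halo_width_px
  x0 <- max(1L, floor(cell$cx - r_max)); x1 <- min(p$width_px,  ceiling(cell$cx + r_max))
  y0 <- max(1L, floor(cell$cy - r_max)); y1 <- min(p$height_px, ceiling(cell$cy + r_max))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(ys * 0, xs - cell$cx, function(a, b) b)  # rows = y, cols = x
  dy <- outer(ys - cell$cy, xs * 0, function(a, b) a)
  ct <- cos(cell$theta); st <- sin(cell$theta)
  u <- (dx * ct + dy * st) / cell$a
  v <- (-dx * st + dy * ct) / cell$b
  rho <- sqrt(u^2 + v^2)
  body <- rho <= 1
  # radial distance (px) past the body edge, scaled by the mean semi-axis
  r_eff <- sqrt(cell$a * cell$b)
  d_out <- (rho - 1) * r_eff
  halo <- ifelse(body, 0, exp(-0.5 * (d_out / p$halo_width_px)^2))
  list(rows = ys, cols = xs, body = body, halo = halo)
}

# fixed-shape low-order polynomial shade-off field with unit max amplitude;
# coefficients drawn once per image from the seeded stream
shade_off_field <- function(p) {
  u <- matrix(rep(seq(-1, 1, length.out = p$width_px), each = p$height_px),
              p$height_px, p$width_px)
  v <- matrix(rep(seq(-1, 1, length.out = p$height_px), p$width_px),
              p$height_px, p$width_px)
  cf <- stats::runif(5, -1, 1)
  f <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * (u^2 - 1 / 3) +
    cf[5] * (v^2 - 1 / 3)
  m <- max(abs(f))
  if (m > 0) f / m else f
}

#' Render a synthetic phase-contrast frame with its ground-truth mask
#'
#' Cells are ellipses placed uniformly at random (optionally with rejection
#' of heavily-overlapping placements), rendered as uniformly dark bodies
#' surrounded by a bright Gaussian-profile halo ring, on a mid-gray
#' background carrying a smooth polynomial shade-off gradient and additive
#' Gaussian noise. The truth mask marks exactly the union of cell-body
#' pixels; halos are excluded. With all artifact amplitudes at zero the
#' image is exactly two-level, so thresholding it reproduces the truth mask
#' pixel for pixel.
#'
#' @param params a [synthetic_image_params()] object.
#' @return A list with components `frame` ([frame_image]) and
#'   `mask` ([confluency_mask] with provenance `"truth"`).
#' @examples
#' out <- generate_cell_image(synthetic_image_params(n_cells = 10, seed = 7))
#' compute_confluency(out$mask)
#' @export
generate_cell_image <- function(params) {
  stopifnot(inherits(params, "synthetic_image_params"))
  p <- params
  with_seed(p$seed, {
    body_mask <- matrix(FALSE, p$height_px, p$width_px)
    halo_acc  <- matrix(0, p$height_px, p$width_px)
    shade <- if (p$shade_off_amplitude > 0)
      p$shade_off_amplitude * shade_off_field(p)
    else matrix(0, p$height_px, p$width_px)
    placed <- 0L
    max_tries <- 30L
    while (placed < p$n_cells) {
      tries <- 0L
      repeat {
        cell <- draw_cell(p)
        fp <- cell_footprint(cell, p)
        tries <- tries + 1L
        if (is.null(fp)) next
        sub <- body_mask[fp$rows, fp$cols, drop = FALSE]
        overlap <- sum(sub & fp$body) / max(1, sum(fp$body))
        if (overlap <= p$max_overlap_frac || tries >= max_tries) break
      }
      body_mask[fp$rows, fp$cols] <- sub | fp$body
      halo_acc[fp$rows, fp$cols] <- pmax(halo_acc[fp$rows, fp$cols], fp$halo)
      placed <- placed + 1L
    }
    halo_acc[body_mask] <- 0  # halo lives strictly outside bodies
    img <- p$background_level + p$body_contrast * body_mask +
      p$halo_amplitude * halo_acc + shade
    if (p$noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, p$noise_sigma)
    img <- clip01(img)
    list(frame = frame_image(img, frame_index = 0L),
         mask = confluency_mask(body_mask * 1, provenance = "truth"))
  })
}
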