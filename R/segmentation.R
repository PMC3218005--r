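#' Segmentation pipeline parameters
#'
#' Controls the restore -> threshold -> dilate pipeline that turns a
#' phase-contrast frame into a confluency mask.
#'
#' The default restoration (`"simplified"`) inverts the frame (cell bodies
#' are dark, so inversion makes them the bright foreground), estimates the
#' smooth background of the inverted image by grayscale morphological
#' opening with a large disc, subtracts it and clips negatives. Inversion
#' turns bright halos into sub-background dips that the clipping removes,
#' and the opening absorbs shade-off gradients, so both phase-contrast
#' artifacts are suppressed. `"none"` skips background removal and only
#' inverts and min-subtracts. Any other string is looked up in the
#' restoration plugin registry (see [register_restoration()]), so a full
#' physics-based restoration can be dropped in without touching the
#' pipeline.
#'
#' @param restoration `"simplified"`, `"none"`, or a registered plugin name.
#' @param background_kernel_px diameter (px) of the opening disc; must
#'   exceed the largest expected cell diameter or cells leak into the
#'   background estimate. Default 40 suits quarter-scale frames; use ~160
#'   at full scale.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold on the restored intensity when
#'   `threshold_method = "fixed"`.
#' @param dilation_radius_px disc radius for the final mask dilation that
#'   captures thin cellular processes (filopodia/lamellipodia). The
#'   instrument-scale default is 8 px; scale it with the frame (2 px at
#'   quarter scale).
#' @param min_dynamic_range restored-intensity range below which the frame
#'   is declared background-only and the mask left empty (guards Otsu
#'   against blank frames).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(restoration = "simplified",
                                background_kernel_px = 40L,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.1,
                                dilation_radius_px = 8L,
                                min_dynamic_range = 0.02) {
  threshold_method <- match.arg(threshold_method)
  if (background_kernel_px < 3) stop("background_kernel_px too small")
  if (dilation_radius_px < 0) stop("dilation_radius_px must be >= 0")
  if (min_dynamic_range < 0) stop("min_dynamic_range must be >= 0")
  structure(
    list(restoration = restoration,
         background_kernel_px = as.integer(background_kernel_px),
         threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         dilation_radius_px = as.integer(dilation_radius_px),
         min_dynamic_range = min_dynamic_range),
    class = "segmentation_params")
}

# ---- restoration plugin registry ------------------------------------------

.restoration_registry <- new.env(parent = emptyenv())

#' Register a restoration plugin
#'
#' A plugin is a function `(pixels, params) -> matrix` taking the raw
#' `[0, 1]` pixel matrix and the [segmentation_params()] and returning a
#' non-negative restored-response matrix of the same shape (background near
#' 0, cell bodies positive).
#'
#' @param name plugin name usable as `segmentation_params(restoration = name)`.
#' @param fun the restoration function.
#' @export
register_restoration <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .restoration_registry)
  invisible(name)
}

# odd brush size closest to (but not above) a requested diameter
odd_brush <- function(d) max(3L, 2L * (as.integer(d) %/% 2L) + 1L)

restore_simplified <- function(px, params) {
  inv <- 1 - px
  brush <- EBImage::makeBrush(odd_brush(params$background_kernel_px), "disc")
  bg <- EBImage::opening(inv, brush)
  pmax(inv - bg, 0)
}

restore_none <- function(px, params) {
  inv <- 1 - px
  inv - min(inv)
}

#' Restore a phase-contrast frame for thresholding
#'
#' Produces a non-negative response map in which background tends to 0 and
#' cell-body regions carry positive response; see [segmentation_params()]
#' for the method. Deterministic for fixed input and parameters, and
#' invariant to adding a constant offset to all pixel intensities.
#'
#' @param frame a [frame_image] or numeric matrix in `[0, 1]`.
#' @param params a [segmentation_params()] object.
#' @return A matrix of restored responses (same shape as the frame).
#' @export
restore_image <- function(frame, params = segmentation_params()) {
  px <- frame_pixels(frame)
  fun <- switch(params$restoration,
    simplified = restore_simplified,
    none = restore_none,
    {
      if (!exists(params$restoration, envir = .restoration_registry))
        stop("unknown restoration plugin: '", params$restoration, "'")
      get(params$restoration, envir = .restoration_registry)
    })
  out <- fun(px, params)
  if (!all(dim(out) == dim(px))) stop("restoration changed the frame shape")
  out
}

#' Threshold a restored frame into a confluency mask
#'
#' Uses Otsu's criterion on a 256-level histogram by default, or a fixed
#' cut. If the restored dynamic range is below `min_dynamic_range` the
#' frame is treated as background-only and the empty mask returned, which
#' keeps Otsu from splitting pure noise on blank frames.
#'
#' @param restored restored response matrix from [restore_image()].
#' @param params a [segmentation_params()] object.
#' @return A [confluency_mask] (pre-dilation).
#' @export
threshold_mask <- function(restored, params = segmentation_params()) {
  px <- frame_pixels(restored)
  rng <- range(px)
  if (diff(rng) < params$min_dynamic_range)
    return(confluency_mask(matrix(0, nrow(px), ncol(px))))
  thr <- if (params$threshold_method == "fixed") params$fixed_threshold else {
    mx <- rng[2]
    EBImage::otsu(px / mx, range = c(0, 1), levels = 256L) * mx
  }
  confluency_mask((px > thr) * 1)
}

#' Dilate a confluency mask with a disc structuring element
#'
#' Captures thin cellular processes around thresholded bodies. Radius 0 is
#' the identity; the output is always a superset of the input, so
#' confluency is non-decreasing in the radius.
#'
#' @param mask a [confluency_mask] or binary matrix.
#' @param radius_px disc radius in pixels (>= 0).
#' @return The dilated [confluency_mask].
#' @export
dilate_mask <- function(mask, radius_px = 8L) {
  if (radius_px < 0) stop("dilation radius must be >= 0")
  m <- as_confluency_mask(mask)
  if (radius_px == 0) return(m)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, "disc")
  confluency_mask(EBImage::dilate(m$labels, brush),
                  provenance = m$provenance, frame_ref = m$frame_ref)
}

#' Confluency of a mask
#'
#' The exact fraction of set pixels: cell-labelled pixels over total pixels.
#'
#' @param mask a [confluency_mask] or binary matrix.
#' @return A fraction in `[0, 1]`.
#' @export
compute_confluency <- function(mask) {
  m <- mask_labels(mask)
  if (length(m) == 0L) stop("empty mask grid")
  sum(m) / length(m)
}

#' Average confluency over an image set
#'
#' Arithmetic mean of per-field-of-view confluency values, the per-time-point
#' summary the monitor tracks (12 fields of view on the source instrument).
#'
#' @param values numeric vector of fractions in `[0, 1]`.
#' @return The mean fraction.
#' @export
average_confluency <- function(values) {
  if (length(values) == 0L) stop("no confluency values to average")
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    stop("confluency values must be finite and in [0, 1]")
  mean(values)
}

#' Overlay a mask on its frame in green
#'
#' @param frame a [frame_image] or matrix.
#' @param mask a congruent [confluency_mask].
#' @param path optional PNG path; written when given.
#' @param weight tint strength in `(0, 1]`.
#' @return An `H x W x 3` RGB array, invisibly when `path` is given.
#' @export
render_overlay <- function(frame, mask, path = NULL, weight = 0.5) {
  px <- frame_pixels(frame)
  m <- mask_labels(mask)
  if (!all(dim(px) == dim(m))) stop("frame/mask shape mismatch")
  r <- px; g <- px; b <- px
  on <- m > 0
  r[on] <- px[on] * (1 - weight)
  b[on] <- px[on] * (1 - weight)
  g[on] <- px[on] * (1 - weight) + weight
  rgb <- array(c(r, g, b), dim = c(dim(px), 3L))
  if (!is.null(path)) { write_rgb(rgb, path); return(invisible(rgb)) }
  rgb
}

#' Segment one frame into a confluency mask and fraction
#'
#' Convenience composition of [restore_image()], [threshold_mask()] and
#' [dilate_mask()].
#'
#' @param frame a [frame_image] or matrix.
#' @param params a [segmentation_params()] object.
#' @return A list with `mask` (dilated [confluency_mask]), `pre_dilation`
#'   mask, and `confluency` (fraction of the dilated mask).
#' @export
segment_frame <- function(frame, params = segmentation_params()) {
  restored <- restore_image(frame, params)
  pre <- threshold_mask(restored, params)
  mask <- dilate_mask(pre, params$dilation_radius_px)
  list(mask = mask, pre_dilation = pre,
       confluency = compute_confluency(mask))
}
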