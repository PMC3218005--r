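#' Read a grayscale frame from TIFF or PNG
#'
#' Intensities are linearly rescaled from the container's dtype range to
#' `[0, 1]` (the readers already do this for integer data); multi-channel
#' images are collapsed by the channel mean.
#'
#' @param path image file (`.tif`/`.tiff` or `.png`).
#' @param ... metadata passed to [frame_image()] (`frame_index`, `fov_id`,
#'   `dish_id`, `timestamp_min`, `pixel_size_um`).
#' @return A [frame_image].
#' @export
read_frame <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image container: .", ext))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  frame_image(clip01(px), ...)
}

# write a [0,1] matrix as 8-bit PNG or 16-bit TIFF
write_frame <- function(pixels, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  pixels <- clip01(frame_pixels(pixels))
  if (format == "png") png::writePNG(pixels, path)
  else tiff::writeTIFF(pixels, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a binary mask from a PNG ({0, 255} or {0, 1} convention)
#'
#' @param path PNG file; any pixel above half range counts as "cell".
#' @param provenance recorded provenance of the mask.
#' @return A [confluency_mask].
#' @export
read_mask <- function(path, provenance = "human") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  confluency_mask((px > 0.5) * 1, provenance = provenance, frame_ref = path)
}

#' Write a binary mask as a {0, 255} PNG
#'
#' @param mask a [confluency_mask] or binary matrix.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask_labels(mask), path)
  invisible(path)
}

# write an H x W x 3 RGB array as PNG
write_rgb <- function(rgb, path) {
  png::writePNG(clip01(rgb), path)
  invisible(path)
}
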