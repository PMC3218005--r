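#' One grayscale phase-contrast frame
#'
#' Lightweight container pairing a pixel matrix (intensities in `[0, 1]`,
#' row = image row, column = image column, origin top-left) with acquisition
#' metadata. All segmentation functions accept either a `frame_image` or a
#' bare numeric matrix.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`.
#' @param pixel_size_um physical pixel size in micrometres (metadata only).
#' @param frame_index 0-based index of the frame in its time-lapse sequence.
#' @param fov_id,dish_id identifiers of the field of view and dish.
#' @param timestamp_min acquisition time in minutes from the start of the run.
#' @return An object of class `frame_image`.
#' @export
frame_image <- function(pixels, pixel_size_um = 1.3, frame_index = 0L,
                        fov_id = "fov_01", dish_id = "dish_1",
                        timestamp_min = 0) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(dim(pixels) < 1L))
    stop("'pixels' must be a non-empty numeric matrix")
  if (!all(is.finite(pixels)))
    stop("frame intensities must be finite")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         frame_index = as.integer(frame_index), fov_id = fov_id,
         dish_id = dish_id, timestamp_min = timestamp_min),
    class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  cat(sprintf("<frame_image> %d x %d px, %.2f um/px, frame %d (%s / %s, t = %g min)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$frame_index, x$dish_id, x$fov_id, x$timestamp_min))
  invisible(x)
}

as_frame_image <- function(x) {
  if (inherits(x, "frame_image")) return(x)
  if (is.matrix(x)) return(frame_image(x))
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a frame image")
}

frame_pixels <- function(x) if (inherits(x, "frame_image")) x$pixels else as.matrix(x)

#' Binary cell/non-cell confluency mask
#'
#' A binary label grid congruent with its source frame: 1 marks pixels
#' covered by cells, 0 marks background. The set-pixel fraction of the mask
#' is the confluency.
#'
#' @param labels matrix of 0/1 (logical matrices are coerced).
#' @param provenance `"computer"` for algorithm output, `"human"` for
#'   digitised manual tracings, `"truth"` for synthetic ground truth.
#' @param frame_ref optional reference to the source frame (e.g. a file name).
#' @return An object of class `confluency_mask`.
#' @export
confluency_mask <- function(labels, provenance = c("computer", "human", "truth"),
                            frame_ref = NULL) {
  provenance <- match.arg(provenance)
  labels <- as.matrix(labels)
  if (any(dim(labels) < 1L)) stop("mask grid must be non-empty")
  storage.mode(labels) <- "double"
  if (!all(labels %in% c(0, 1)))
    stop("mask labels must be binary (0/1)")
  structure(list(labels = labels, provenance = provenance,
                 frame_ref = frame_ref),
            class = "confluency_mask")
}

#' @export
print.confluency_mask <- function(x, ...) {
  cat(sprintf("<confluency_mask> %d x %d px, %s, confluency %.4f\n",
              nrow(x$labels), ncol(x$labels), x$provenance,
              mean(x$labels)))
  invisible(x)
}

as_confluency_mask <- function(x, provenance = "computer") {
  if (inherits(x, "confluency_mask")) return(x)
  if (is.matrix(x)) return(confluency_mask(x, provenance))
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a confluency mask")
}

mask_labels <- function(x) {
  if (inherits(x, "confluency_mask")) x$labels
  else { m <- as.matrix(x); storage.mode(m) <- "double"; m }
}

#' Confluency time series
#'
#' @param frame integer frame indices (0-based, strictly increasing).
#' @param value confluency fractions in `[0, 1]`.
#' @param frame_interval_min nominal frame spacing in minutes.
#' @param time_min acquisition times; defaults to `frame * frame_interval_min`.
#' @return A data frame of class `confluency_series` with columns
#'   `frame`, `time_min`, `value` and attribute `frame_interval_min`.
#' @export
confluency_series <- function(frame, value, frame_interval_min = 5,
                              time_min = frame * frame_interval_min) {
  frame <- as.integer(frame)
  if (length(frame) < 1L) stop("empty series")
  if (is.unsorted(frame, strictly = TRUE))
    stop("frame indices must be strictly increasing")
  if (any(!is.finite(value)) || any(value < 0 | value > 1))
    stop("confluency values must be finite and in [0, 1]")
  structure(
    data.frame(frame = frame, time_min = as.numeric(time_min),
               value = as.numeric(value)),
    frame_interval_min = frame_interval_min,
    class = c("confluency_series", "data.frame"))
}

as_confluency_series <- function(x, frame_interval_min = 5) {
  if (inherits(x, "confluency_series")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("frame", "value") %in% names(x)))
    tm <- if ("time_min" %in% names(x)) x$time_min else x$frame * frame_interval_min
    return(confluency_series(x$frame, x$value, frame_interval_min, tm))
  }
  if (is.numeric(x))
    return(confluency_series(seq_along(x) - 1L, x, frame_interval_min))
  stop("cannot interpret object as a confluency series")
}

series_interval <- function(s) {
  iv <- attr(s, "frame_interval_min")
  if (is.null(iv)) {
    iv <- if (nrow(s) > 1) stats::median(diff(s$time_min) / diff(s$frame)) else 5
  }
  iv
}

# run an expression with a locally-seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
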