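#' Pixel-level confusion counts between a computer and a reference mask
#'
#' A pixel labelled "cell" in both masks is a true positive; in the
#' prediction only, a false positive; in the reference only, a false
#' negative; in neither, a true negative. The four counts always sum to the
#' total pixel count.
#'
#' @param pred computer-generated [confluency_mask] (or binary matrix).
#' @param ref reference (e.g. digitised human tracing) mask, same shape.
#' @return An object of class `seg_confusion` with fields `TP`, `FP`,
#'   `FN`, `TN`, `total`.
#' @export
confusion_pixels <- function(pred, ref) {
  p <- mask_labels(pred) > 0
  r <- mask_labels(ref) > 0
  if (!all(dim(p) == dim(r))) stop("mask shape mismatch")
  tp <- sum(p & r)
  fp <- sum(p & !r)
  fn <- sum(!p & r)
  tn <- length(p) - tp - fp - fn
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn, total = length(p)),
            class = "seg_confusion")
}

#' @export
print.seg_confusion <- function(x, ...) {
  cat(sprintf("<seg_confusion> TP %d  FP %d  FN %d  TN %d  (n = %d px)\n",
              x$TP, x$FP, x$FN, x$TN, x$total))
  if (x$TP + x$FP > 0) cat(sprintf("  precision %.4f\n", precision(x)))
  if (x$TP + x$FN > 0) cat(sprintf("  recall    %.4f\n", recall(x)))
  invisible(x)
}

#' Segmentation precision: TP / (TP + FP)
#'
#' @param x a `seg_confusion` object.
#' @return Fraction in `[0, 1]`; errors when no pixel was predicted
#'   positive (the metric is undefined).
#' @export
precision <- function(x) {
  stopifnot(inherits(x, "seg_confusion"))
  if (x$TP + x$FP == 0) stop("precision undefined: no predicted-positive pixels")
  x$TP / (x$TP + x$FP)
}

#' Segmentation recall: TP / (TP + FN)
#'
#' @param x a `seg_confusion` object.
#' @return Fraction in `[0, 1]`; errors when the reference is empty.
#' @export
recall <- function(x) {
  stopifnot(inherits(x, "seg_confusion"))
  if (x$TP + x$FN == 0) stop("recall undefined: no reference-positive pixels")
  x$TP / (x$TP + x$FN)
}

#' Colour-coded evaluation overlay
#'
#' Yellow = true positive, green = false positive, red = false negative,
#' black = true negative.
#'
#' @param pred,ref congruent masks, as in [confusion_pixels()].
#' @param path optional PNG output path.
#' @return An `H x W x 3` RGB array (invisibly when written to `path`).
#' @export
evaluation_overlay <- function(pred, ref, path = NULL) {
  p <- mask_labels(pred) > 0
  r <- mask_labels(ref) > 0
  if (!all(dim(p) == dim(r))) stop("mask shape mismatch")
  red <- (p & r) | (!p & r)          # yellow + red share the red channel
  green <- (p & r) | (p & !r)        # yellow + green share the green channel
  rgb <- array(0, dim = c(dim(p), 3L))
  rgb[, , 1] <- red * 1
  rgb[, , 2] <- green * 1
  if (!is.null(path)) { write_rgb(rgb, path); return(invisible(rgb)) }
  rgb
}

#' Evaluate a set of computer masks against reference masks
#'
#' Reports per-image counts and metrics plus two aggregations: the
#' per-image mean with its standard error (the default headline numbers,
#' mirroring evaluation over a small set of manually traced images), and
#' pooled-pixel metrics computed on the summed confusion counts.
#'
#' @param pred list of computer masks (or a directory of PNG masks).
#' @param ref list of reference masks (or a directory; files are paired by
#'   sorted name).
#' @param overlay_dir optional directory for per-image evaluation overlays.
#' @return A list of class `seg_evaluation`: `per_image` data frame,
#'   `mean_precision`, `sem_precision`, `mean_recall`, `sem_recall`,
#'   `pooled` (a `seg_confusion`), `pooled_precision`, `pooled_recall`.
#' @export
evaluate_masks <- function(pred, ref, overlay_dir = NULL) {
  load_dir <- function(d, prov) {
    files <- sort(list.files(d, pattern = "\\.png$", full.names = TRUE))
    stats::setNames(lapply(files, read_mask, provenance = prov),
                    basename(files))
  }
  if (is.character(pred) && length(pred) == 1L && dir.exists(pred))
    pred <- load_dir(pred, "computer")
  if (is.character(ref) && length(ref) == 1L && dir.exists(ref))
    ref <- load_dir(ref, "human")
  if (length(pred) != length(ref) || length(pred) == 0L)
    stop("need equally many (>= 1) predicted and reference masks")
  ids <- names(pred)
  if (is.null(ids)) ids <- sprintf("image_%02d", seq_along(pred))
  if (!is.null(overlay_dir))
    dir.create(overlay_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(pred), function(i) {
    cf <- confusion_pixels(pred[[i]], ref[[i]])
    if (!is.null(overlay_dir))
      evaluation_overlay(pred[[i]], ref[[i]],
                         file.path(overlay_dir, paste0("eval_", ids[i], ".png")))
    data.frame(image = ids[i], TP = cf$TP, FP = cf$FP, FN = cf$FN, TN = cf$TN,
               precision = precision(cf), recall = recall(cf))
  })
  per_image <- do.call(rbind, rows)
  pooled <- structure(list(TP = sum(per_image$TP), FP = sum(per_image$FP),
                           FN = sum(per_image$FN), TN = sum(per_image$TN),
                           total = sum(per_image$TP + per_image$FP +
                                         per_image$FN + per_image$TN)),
                      class = "seg_confusion")
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(list(per_image = per_image,
                 mean_precision = mean(per_image$precision),
                 sem_precision = sem(per_image$precision),
                 mean_recall = mean(per_image$recall),
                 sem_recall = sem(per_image$recall),
                 pooled = pooled,
                 pooled_precision = precision(pooled),
                 pooled_recall = recall(pooled)),
            class = "seg_evaluation")
}

#' @export
print.seg_evaluation <- function(x, ...) {
  cat(sprintf("<seg_evaluation> %d image(s)\n", nrow(x$per_image)))
  cat(sprintf("  per-image precision %.3f +/- %.3f, recall %.3f +/- %.3f (mean +/- SEM)\n",
              x$mean_precision, x$sem_precision, x$mean_recall, x$sem_recall))
  cat(sprintf("  pooled-pixel precision %.3f, recall %.3f\n",
              x$pooled_precision, x$pooled_recall))
  invisible(x)
}
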