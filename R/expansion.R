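#' Start a serial-expansion (cell calculator) run
#'
#' Bookkeeping for expanding a culture toward a target cell number by
#' serial passaging at a fixed subculture ratio: each passage, every dish
#' is harvested, counted with a hemocytometer, and — if the target is not
#' yet met — re-plated at low density into `ratio` times as many dishes.
#'
#' @param target_cells target total cell number (> 0).
#' @param initial_dishes number of dishes at passage 1 (> 0).
#' @param subculture_ratio dishes seeded per harvested dish (default 8,
#'   i.e. a 1:8 split).
#' @return An object of class `expansion_state` with `decision` of
#'   `"continue"`; see [record_harvest()].
#' @examples
#' st <- expansion_start(50e6, 4)
#' st <- record_harvest(st, 19.92e4)
#' st <- record_harvest(st, 19.92e4)
#' st <- record_harvest(st, 19.92e4)
#' st
#' @export
expansion_start <- function(target_cells, initial_dishes,
                            subculture_ratio = 8L) {
  if (!is.finite(target_cells) || target_cells <= 0)
    stop("target_cells must be positive")
  if (!is.finite(initial_dishes) || initial_dishes < 1)
    stop("initial_dishes must be >= 1")
  if (subculture_ratio < 1) stop("subculture_ratio must be >= 1")
  structure(
    list(target_cells = target_cells,
         dishes_current = as.integer(initial_dishes),
         passage_number = 1L,
         subculture_ratio = as.integer(subculture_ratio),
         history = data.frame(passage = integer(0), dishes = integer(0),
                              cells_per_dish = numeric(0),
                              total_harvested = numeric(0)),
         decision = "continue",
         message = "Continue experiment"),
    class = "expansion_state")
}

#' Record a passage harvest and decide whether to continue
#'
#' The total harvest of the current passage is `dishes * cells_per_dish`
#' (the hemocytometer count is a per-dish average). If it meets the target
#' the run stops ("Stop experiment"); otherwise the cells are split 1:ratio
#' into `dishes * ratio` dishes and the run continues ("Continue
#' experiment"). Only the latest harvest is compared against the target —
#' cells are re-plated, not banked.
#'
#' @param state an [expansion_start()] state with `decision = "continue"`.
#' @param cells_per_dish average cells harvested per dish (>= 0).
#' @return The updated `expansion_state`.
#' @export
record_harvest <- function(state, cells_per_dish) {
  stopifnot(inherits(state, "expansion_state"))
  if (state$decision == "stop")
    stop("run already stopped; start a new expansion")
  if (!is.finite(cells_per_dish) || cells_per_dish < 0)
    stop("cells_per_dish must be non-negative")
  total <- state$dishes_current * cells_per_dish
  state$history <- rbind(state$history,
                         data.frame(passage = state$passage_number,
                                    dishes = state$dishes_current,
                                    cells_per_dish = cells_per_dish,
                                    total_harvested = total))
  if (total >= state$target_cells) {
    state$decision <- "stop"
    state$message <- "Stop experiment"
  } else {
    state$decision <- "continue"
    state$message <- "Continue experiment"
    state$dishes_current <- state$dishes_current * state$subculture_ratio
    state$passage_number <- state$passage_number + 1L
  }
  state
}

#' @export
print.expansion_state <- function(x, ...) {
  cat(sprintf("<expansion_state> target %.4g cells, 1:%d splits\n",
              x$target_cells, x$subculture_ratio))
  if (nrow(x$history) > 0) {
    h <- x$history
    for (i in seq_len(nrow(h)))
      cat(sprintf("  passage %d: %d dishes x %.4g cells/dish = %.4g cells\n",
                  h$passage[i], h$dishes[i], h$cells_per_dish[i],
                  h$total_harvested[i]))
  }
  cat(sprintf("  %s (passage %d, %d dish(es) in play)\n",
              x$message, x$passage_number, x$dishes_current))
  invisible(x)
}

#' Passages needed to reach a target yield at constant per-dish harvest
#'
#' The smallest passage number `p >= 1` with
#' `initial_dishes * ratio^(p-1) * yield_per_dish >= target`: the
#' closed-form ceiling of a logarithm, verified and corrected against the
#' direct inequality to be exact under floating point.
#'
#' @param target target total cell number (> 0).
#' @param initial_dishes dishes at passage 1 (> 0).
#' @param yield_per_dish cells harvested per dish (> 0, assumed constant).
#' @param ratio subculture ratio (default 8).
#' @return Integer passage count.
#' @examples
#' passages_to_target(50e6, 4, 19.92e4)  # 3
#' @export
passages_to_target <- function(target, initial_dishes, yield_per_dish,
                               ratio = 8L) {
  if (target <= 0 || initial_dishes <= 0 || yield_per_dish <= 0 || ratio < 1)
    stop("all arguments must be positive (ratio >= 1)")
  first <- initial_dishes * yield_per_dish
  if (first >= target) return(1L)
  if (ratio == 1) stop("ratio 1 cannot grow the culture toward the target")
  p <- 1L + ceiling(log(target / first) / log(ratio))
  # correct the closed form against the exact inequality
  harvest <- function(q) initial_dishes * ratio^(q - 1) * yield_per_dish
  while (p > 1L && harvest(p - 1L) >= target) p <- p - 1L
  while (harvest(p) < target) p <- p + 1L
  as.integer(p)
}
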