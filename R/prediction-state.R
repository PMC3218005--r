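#' Create an empty prediction-tracking state
#'
#' Tracks, per frame, the observed confluency, the forecast made one
#' horizon earlier for that frame, the signed forecast error and its
#' square, and a trailing-window sample variance of the signed errors (the
#' variance trace used to judge when forecasts have become reliable).
#'
#' @param var_window number of trailing error records entering the sample
#'   variance (default 48, i.e. 4 h of 5-min frames).
#' @return An object of class `prediction_state`.
#' @export
prediction_state <- function(var_window = 48L) {
  structure(list(var_window = as.integer(var_window),
                 observed = numeric(0), forecast = numeric(0),
                 error = numeric(0), squared_error = numeric(0),
                 variance_trace = numeric(0)),
            class = "prediction_state")
}

#' Record one (forecast, observation) pair and update the variance trace
#'
#' Appends the signed error `forecast - observed` and its square, and
#' recomputes the trailing-window sample variance of the signed errors
#' (`NA` until two records exist).
#'
#' @param state a [prediction_state()] object.
#' @param observed measured average confluency at the current frame.
#' @param forecast_H_earlier the forecast for this frame made one horizon
#'   earlier; pass `NA` when no forecast was available (warm-up), which
#'   records the observation without an error entry.
#' @return The updated `prediction_state`.
#' @export
update_variance <- function(state, observed, forecast_H_earlier) {
  stopifnot(inherits(state, "prediction_state"))
  state$observed <- c(state$observed, observed)
  state$forecast <- c(state$forecast, forecast_H_earlier)
  if (is.finite(forecast_H_earlier)) {
    err <- forecast_H_earlier - observed
    state$error <- c(state$error, err)
    state$squared_error <- c(state$squared_error, err^2)
  }
  ne <- length(state$error)
  v <- if (ne >= 2L)
    stats::var(state$error[max(1L, ne - state$var_window + 1L):ne])
  else NA_real_
  state$variance_trace <- c(state$variance_trace, v)
  state
}

#' @export
print.prediction_state <- function(x, ...) {
  nv <- length(x$variance_trace)
  cat(sprintf("<prediction_state> %d frame(s), %d error record(s)",
              length(x$observed), length(x$error)))
  if (nv > 0 && is.finite(x$variance_trace[nv]))
    cat(sprintf(", current variance %.3g", x$variance_trace[nv]))
  cat("\n")
  invisible(x)
}

#' Rolling horizon-ahead forecasts over a series
#'
#' For every frame for which an observation exists one horizon after an
#' available fit window, fits the family on the trailing `window_frames`
#' points ending at the forecast origin and evaluates the forecast at the
#' target frame. This replays what the live monitor would have predicted.
#'
#' @param series a [confluency_series] (may be subsampled; the horizon must
#'   then be a multiple of the series stride).
#' @param window_frames trailing window length in points.
#' @param family model family, see [fit_growth_model()].
#' @param horizon_min forecast horizon in minutes (default 240).
#' @param min_points minimum points required before a fit is attempted
#'   (default 10).
#' @return A data frame with columns `frame`, `time_min`, `observed`,
#'   `forecast` (one row per evaluable target frame).
#' @export
rolling_forecast <- function(series, window_frames = 300L, family = "poly2",
                             horizon_min = 240, min_points = 10L) {
  series <- as_confluency_series(series)
  interval <- series_interval(series)
  h_frames <- as.integer(round(horizon_min / interval))
  n <- nrow(series)
  origin_row <- match(series$frame - h_frames, series$frame)
  npar <- n_fit_params(family)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    j <- origin_row[i]
    if (is.na(j) || j < max(min_points, npar)) next
    lo <- max(1L, j - window_frames + 1L)
    fit <- fit_growth_model(series[lo:j, , drop = FALSE],
                            window_frames = window_frames, family = family)
    out[[i]] <- data.frame(frame = series$frame[i],
                           time_min = series$time_min[i],
                           observed = series$value[i],
                           forecast = forecast(fit, series$time_min[i]))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(frame = integer(0), time_min = numeric(0),
                      observed = numeric(0), forecast = numeric(0)))
  do.call(rbind, out)
}

#' Compare growth-model families by horizon-ahead forecast RMSE
#'
#' Ranks candidate families by the error that matters operationally: the
#' RMSE of horizon-ahead forecasts against the later observations, pooled
#' over all evaluable frames of the series. (In-window RMSE cannot rank
#' nested polynomials, since a higher order never fits worse in-window.)
#' A family that fails to fit (e.g. exponential on non-positive data)
#' gets `NA` with the error message in `note` and sorts last.
#'
#' Only forecasts issued after the monitor's warm-up enter the comparison
#' (`warmup_points`, default 200 observed frames at the forecast origin):
#' the monitor flags earlier forecasts as unreliable and never acts on
#' them, so ranking families on them would select a model for a regime the
#' system ignores by design.
#'
#' @param series a [confluency_series].
#' @param families character vector of families to compare.
#' @param window_frames,horizon_min as in [rolling_forecast()].
#' @param warmup_points observations that must precede a forecast origin
#'   for it to count toward the RMSE.
#' @return A data frame of class `model_comparison` with columns `family`,
#'   `forecast_rmse`, `n_eval`, `note`, sorted by ascending RMSE.
#' @export
compare_models <- function(series,
                           families = c("poly1", "poly2", "poly3",
                                        "logarithmic", "exponential"),
                           window_frames = 300L, horizon_min = 240,
                           warmup_points = 200L) {
  series <- as_confluency_series(series)
  families <- match.arg(families, GROWTH_FAMILIES, several.ok = TRUE)
  rows <- lapply(families, function(fam) {
    res <- tryCatch({
      rf <- rolling_forecast(series, window_frames, fam, horizon_min,
                             min_points = warmup_points)
      if (nrow(rf) < 10L)
        stop("fewer than 10 evaluable forecasts; series too short")
      data.frame(family = fam,
                 forecast_rmse = rmse(rf$forecast, rf$observed),
                 n_eval = nrow(rf), note = "")
    }, error = function(e)
      data.frame(family = fam, forecast_rmse = NA_real_, n_eval = 0L,
                 note = conditionMessage(e)))
    res
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(is.na(tab$forecast_rmse), tab$forecast_rmse), ]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Forecast RMSE with full-rate versus subsampled series
#'
#' Runs the rolling poly2 forecast RMSE on the full series and on every
#' `stride`-th frame (window scaled to `window_frames / stride` points, so
#' both cover the same time span), quantifying how much forecast accuracy
#' the lower acquisition rate costs.
#'
#' Forecast origins are gated at the same warm-up span (in frames) for
#' both rates, so the two RMSEs cover the same portion of the run.
#'
#' @param series a [confluency_series].
#' @param stride keep every `stride`-th frame (default 6, i.e. 30-min
#'   sampling from 5-min frames).
#' @param window_frames,horizon_min as in [rolling_forecast()];
#'   `horizon_min` should be a multiple of `stride * frame_interval`.
#' @param warmup_frames frames that must precede a forecast origin
#'   (applied as `warmup_frames / stride` points on the strided series).
#' @return A list with `rmse_full`, `rmse_strided`, `stride`.
#' @export
subsample_compare <- function(series, stride = 6L, window_frames = 300L,
                              horizon_min = 240, warmup_frames = 200L) {
  series <- as_confluency_series(series)
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (stride > nrow(series)) stop("stride larger than the series")
  rf_full <- rolling_forecast(series, window_frames, "poly2", horizon_min,
                              min_points = warmup_frames)
  sub <- series[seq(1L, nrow(series), by = stride), , drop = FALSE]
  sub <- confluency_series(sub$frame, sub$value,
                           frame_interval_min = series_interval(series),
                           time_min = sub$time_min)
  w_sub <- max(3L, as.integer(round(window_frames / stride)))
  rf_sub <- rolling_forecast(sub, w_sub, "poly2", horizon_min,
                             min_points = max(4L, as.integer(ceiling(
                               warmup_frames / stride))))
  if (nrow(rf_full) == 0L || nrow(rf_sub) == 0L)
    stop("series too short for subsampling comparison")
  list(rmse_full = rmse(rf_full$forecast, rf_full$observed),
       rmse_strided = rmse(rf_sub$forecast, rf_sub$observed),
       stride = stride)
}
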