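#' Monitoring configuration
#'
#' Bundles the run-level constants of the monitor: the confluency threshold
#' that triggers subculture, the advance-notice horizon, frame timing, the
#' fit window, the warm-up gate below which forecasts are considered
#' unreliable, and the expected number of fields of view per time point.
#'
#' @param threshold confluency threshold in `(0, 1]` (default 0.5, chosen
#'   to keep myoblasts below the density at which they start fusing).
#' @param horizon_min advance-notice / forecast horizon, minutes (default
#'   240 = 4 h); must be a positive multiple of `frame_interval_min`.
#' @param frame_interval_min minutes between time points (default 5).
#' @param window_frames trailing fit window, frames (default 300).
#' @param min_frames warm-up: frames required before forecasts are trusted
#'   and the advance alert may fire (default 200).
#' @param fovs_per_timepoint fields of view imaged per time point
#'   (default 12).
#' @param var_window trailing window of the forecast-error variance trace,
#'   frames (default 48 = one horizon).
#' @return A list of class `monitor_config`.
#' @export
monitor_config <- function(threshold = 0.5, horizon_min = 240,
                           frame_interval_min = 5, window_frames = 300L,
                           min_frames = 200L, fovs_per_timepoint = 12L,
                           var_window = 48L) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (horizon_min <= 0 || horizon_min %% frame_interval_min != 0)
    stop("horizon_min must be a positive multiple of frame_interval_min")
  structure(list(threshold = threshold, horizon_min = horizon_min,
                 frame_interval_min = frame_interval_min,
                 window_frames = as.integer(window_frames),
                 min_frames = as.integer(min_frames),
                 fovs_per_timepoint = as.integer(fovs_per_timepoint),
                 var_window = as.integer(var_window)),
            class = "monitor_config")
}

#' Create (or resume) a notifier state
#'
#' The notifier is an at-most-once event machine per culture run: one
#' advance alert (`PRE_ALERT`) and one measured-threshold reminder
#' (`THRESHOLD_REACHED`). Its state can be persisted to JSON so a restarted
#' process never re-emits an event.
#'
#' @param run_id identifier of the culture run.
#' @param path optional JSON state file; if it exists the state is loaded
#'   from it (and [save_notifier_state()] will write back to it).
#' @return A list of class `notifier_state`.
#' @export
notifier_state <- function(run_id = "run", path = NULL) {
  if (!is.null(path) && file.exists(path)) {
    st <- load_notifier_state(path)
    st$path <- path
    return(st)
  }
  structure(list(run_id = run_id, path = path,
                 pre_alert = NULL, threshold_reached = NULL,
                 last_frame = -Inf, dispatched = character(0)),
            class = "notifier_state")
}

#' Persist / load notifier state as JSON
#'
#' @param state a `notifier_state`.
#' @param path JSON file path; defaults to the path the state was created
#'   with.
#' @return `save_notifier_state` returns the path invisibly;
#'   `load_notifier_state` returns the state.
#' @export
save_notifier_state <- function(state, path = state$path) {
  stopifnot(inherits(state, "notifier_state"), !is.null(path))
  x <- unclass(state)
  x$path <- NULL
  x$last_frame <- if (is.finite(x$last_frame)) x$last_frame else NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_notifier_state
#' @export
load_notifier_state <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(run_id = x$run_id, path = path,
                 pre_alert = x$pre_alert, threshold_reached = x$threshold_reached,
                 last_frame = if (is.null(x$last_frame)) -Inf else x$last_frame,
                 dispatched = as.character(x$dispatched %||% character(0))),
            class = "notifier_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_event <- function(kind, state, frame_index, time_min, avg, crossing, msg) {
  structure(list(kind = kind, run_id = state$run_id,
                 frame_index = frame_index, time_min = time_min,
                 average_confluency = avg,
                 predicted_crossing_time_min = crossing,
                 message = msg),
            class = "notification_event")
}

#' @export
print.notification_event <- function(x, ...) {
  cat(sprintf("[%s] frame %d (t = %g min): %s\n",
              x$kind, x$frame_index, x$time_min, x$message))
  invisible(x)
}

#' Advance the notifier by one observed time point
#'
#' Emits `PRE_ALERT` the first time the warm-up has passed
#' (`frame_index >= min_frames`) and the predicted crossing lies within the
#' advance horizon; emits `THRESHOLD_REACHED` the first time the measured
#' average confluency itself reaches the threshold (no warm-up gate: it is
#' a measurement, not a forecast). Each event fires at most once per run,
#' including across process restarts when the state is persisted.
#'
#' @param state a [notifier_state()] object.
#' @param now_min current time, minutes.
#' @param frame_index current frame index (must be strictly increasing
#'   across calls).
#' @param avg_confluency measured average confluency at this time point.
#' @param predicted_crossing_min predicted threshold-crossing time in
#'   minutes, or `NA` when no crossing is predicted.
#' @param config a [monitor_config()] object.
#' @return A list with `state` (updated) and `events` (possibly empty list
#'   of `notification_event`s).
#' @export
notifier_update <- function(state, now_min, frame_index, avg_confluency,
                            predicted_crossing_min = NA_real_,
                            config = monitor_config()) {
  stopifnot(inherits(state, "notifier_state"),
            inherits(config, "monitor_config"))
  if (frame_index <= state$last_frame)
    stop(sprintf("out-of-order frame %d (last processed %g)",
                 frame_index, state$last_frame))
  if (!is.finite(avg_confluency) || avg_confluency < 0 || avg_confluency > 1)
    stop("avg_confluency must be in [0, 1]")
  state$last_frame <- frame_index
  events <- list()

  if (is.null(state$pre_alert) && frame_index >= config$min_frames &&
      is.finite(predicted_crossing_min) &&
      predicted_crossing_min - now_min <= config$horizon_min) {
    ev <- new_event(
      "PRE_ALERT", state, frame_index, now_min, avg_confluency,
      predicted_crossing_min,
      sprintf(paste0("Confluency predicted to reach %.2f at t = %.0f min ",
                     "(in %.0f min); prepare for subculture."),
              config$threshold, predicted_crossing_min,
              predicted_crossing_min - now_min))
    state$pre_alert <- list(frame_index = frame_index, time_min = now_min,
                            average_confluency = avg_confluency,
                            predicted_crossing_time_min = predicted_crossing_min)
    events <- c(events, list(ev))
  }

  if (is.null(state$threshold_reached) &&
      avg_confluency >= config$threshold) {
    ev <- new_event(
      "THRESHOLD_REACHED", state, frame_index, now_min, avg_confluency,
      if (is.finite(predicted_crossing_min)) predicted_crossing_min else NA_real_,
      sprintf("Average confluency %.3f has reached the threshold %.2f; subculture now.",
              avg_confluency, config$threshold))
    state$threshold_reached <- list(frame_index = frame_index,
                                    time_min = now_min,
                                    average_confluency = avg_confluency)
    events <- c(events, list(ev))
  }

  if (!is.null(state$path)) save_notifier_state(state)
  list(state = state, events = events)
}

# ---- channels --------------------------------------------------------------

#' Notification channels
#'
#' A channel is a list with a `name` and a `send(event)` function. The log
#' channel appends one ISO-timestamped line per event to a text file and is
#' always available. The SMTP channel is a configuration-gated stub: it
#' validates its configuration and refuses to send unless `enabled = TRUE`
#' and a host is configured, standing in for a real mail relay.
#'
#' @param path events log file (created if needed).
#' @return A channel object.
#' @export
log_channel <- function(path) {
  force(path)
  list(name = "log", send = function(event) {
    line <- sprintf("%s\t%s\tframe=%d\tt_min=%g\tavg=%.4f\tcrossing_min=%s\t%s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    event$kind, event$frame_index, event$time_min,
                    event$average_confluency,
                    ifelse(is.finite(event$predicted_crossing_time_min %||% NA_real_),
                           sprintf("%.1f", event$predicted_crossing_time_min), "NA"),
                    event$message)
    cat(line, "\n", sep = "", file = path, append = TRUE)
    invisible(TRUE)
  })
}

#' @rdname log_channel
#' @param host,port,from,to SMTP relay configuration.
#' @param enabled must be explicitly `TRUE` for the channel to attempt
#'   delivery; defaults to disabled so automated runs never send mail.
#' @export
smtp_channel <- function(host = NULL, port = 587L, from = NULL, to = NULL,
                         enabled = FALSE) {
  list(name = "smtp", send = function(event) {
    if (!isTRUE(enabled) || is.null(host) || is.null(to))
      stop("smtp channel not configured (set host/to and enabled = TRUE)")
    stop("smtp delivery not implemented in this build; use the log channel")
  })
}

#' Dispatch an event through a set of channels
#'
#' Delivery is attempted on every channel; per-channel failures are
#' captured in the report and never abort the run. Dispatch is at-most-once
#' per `(run, event kind)`: when a `notifier_state` is supplied, a repeat
#' dispatch of the same event kind is refused.
#'
#' @param event a `notification_event`.
#' @param channels list of channel objects (see [log_channel()]).
#' @param state optional [notifier_state()] used for the idempotency key;
#'   returned updated in the result.
#' @return A list with `report` (data frame: channel, ok, detail) and
#'   `state`.
#' @export
dispatch <- function(event, channels, state = NULL) {
  stopifnot(inherits(event, "notification_event"), length(channels) >= 1L)
  key <- paste(event$run_id, event$kind, sep = ":")
  if (!is.null(state) && key %in% state$dispatched) {
    return(list(report = data.frame(channel = vapply(channels, `[[`, "", "name"),
                                    ok = FALSE,
                                    detail = "duplicate dispatch refused"),
                state = state))
  }
  rows <- lapply(channels, function(ch) {
    res <- tryCatch({ ch$send(event); list(ok = TRUE, detail = "delivered") },
                    error = function(e) list(ok = FALSE,
                                             detail = conditionMessage(e)))
    data.frame(channel = ch$name, ok = res$ok, detail = res$detail)
  })
  if (!is.null(state)) {
    state$dispatched <- c(state$dispatched, key)
    if (!is.null(state$path)) save_notifier_state(state)
  }
  list(report = do.call(rbind, rows), state = state)
}
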