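#' @name pipeline
#' @title Batch and watch-mode confluency monitoring pipeline
#'
#' @description
#' [run_batch()] replays an on-disk time-lapse dataset through the full
#' monitoring loop: per time point it segments every field of view,
#' averages the confluency, updates the sliding-window growth fit and
#' horizon-ahead forecast, updates the forecast-error variance trace, and
#' feeds the notifier. [run_watch()] does the same incrementally, polling
#' the input directory for newly arrived frames, and produces numerically
#' identical outputs on identical inputs.
#'
#' Outputs in `out_dir`: `confluency.csv` (frame, time, per-FOV values,
#' average), `predictions.csv` (forecast, predicted crossing, variance),
#' `events.log`, `state.json`, and overlay PNGs of the final time point
#' under `overlays/`.
#'
#' The input layout is `<dir>/<dish>/<fov>/frame_<k>.png|tif`, or a
#' `manifest.json` as written by [generate_timelapse_dataset()]. A time
#' point missing some fields of view is averaged over the ones present
#' (with a warning); an unreadable image is skipped the same way.
NULL

# discover frames on disk -> data.frame(frame, fov, dish, path)
scan_frames <- function(input_dir) {
  files <- list.files(input_dir, pattern = "^frame_\\d+\\.(png|tif|tiff)$",
                      recursive = TRUE, full.names = FALSE)
  if (length(files) == 0L)
    return(data.frame(frame = integer(0), fov = character(0),
                      dish = character(0), path = character(0)))
  parts <- strsplit(files, "/", fixed = TRUE)
  keep <- lengths(parts) >= 3L
  parts <- parts[keep]; files <- files[keep]
  data.frame(
    frame = as.integer(sub("^frame_(\\d+)\\..*$", "\\1",
                           vapply(parts, function(p) p[length(p)], ""))),
    fov = vapply(parts, function(p) p[length(p) - 1L], ""),
    dish = vapply(parts, function(p) p[length(p) - 2L], ""),
    path = file.path(input_dir, files))
}

new_pipeline_ctx <- function(input_dir, out_dir, config, seg, run_id,
                             channels) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctx <- new.env(parent = emptyenv())
  ctx$input_dir <- input_dir
  ctx$out_dir <- out_dir
  ctx$config <- config
  ctx$seg <- seg
  ctx$conf_csv <- file.path(out_dir, "confluency.csv")
  ctx$pred_csv <- file.path(out_dir, "predictions.csv")
  ctx$events_log <- file.path(out_dir, "events.log")
  ctx$channels <- if (is.null(channels)) list(log_channel(ctx$events_log))
                  else channels
  ctx$notif <- notifier_state(run_id, path = file.path(out_dir, "state.json"))
  ctx$pred_state <- prediction_state(config$var_window)
  ctx$frames <- integer(0); ctx$times <- numeric(0); ctx$values <- numeric(0)
  ctx$pending <- new.env(parent = emptyenv())  # target frame -> forecast
  ctx$events <- list()
  ctx$fov_ids <- NULL
  ctx$header_written <- FALSE
  if (!file.exists(ctx$events_log)) file.create(ctx$events_log)
  ctx
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))

process_timepoint <- function(ctx, frame_idx, rows) {
  cfg <- ctx$config
  if (is.null(ctx$fov_ids)) ctx$fov_ids <- sort(unique(rows$fov))
  vals <- stats::setNames(rep(NA_real_, length(ctx$fov_ids)), ctx$fov_ids)
  last_seg <- list()
  for (i in seq_len(nrow(rows))) {
    fov <- rows$fov[i]
    if (!fov %in% ctx$fov_ids) next
    res <- tryCatch({
      fr <- read_frame(rows$path[i], frame_index = frame_idx, fov_id = fov,
                       dish_id = rows$dish[i],
                       timestamp_min = frame_idx * cfg$frame_interval_min)
      segment_frame(fr, ctx$seg)
    }, error = function(e) {
      warning(sprintf("frame %d / %s unreadable (%s); skipping",
                      frame_idx, fov, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      vals[fov] <- res$confluency
      last_seg[[fov]] <- list(path = rows$path[i], mask = res$mask)
    }
  }
  present <- sum(is.finite(vals))
  if (present == 0L) {
    warning(sprintf("frame %d: no readable field of view; skipped", frame_idx),
            call. = FALSE)
    return(invisible(NULL))
  }
  if (present < length(ctx$fov_ids))
    warning(sprintf("frame %d: only %d of %d fields of view present; averaging over those",
                    frame_idx, present, length(ctx$fov_ids)), call. = FALSE)
  avg <- average_confluency(vals[is.finite(vals)])
  now_min <- frame_idx * cfg$frame_interval_min
  ctx$frames <- c(ctx$frames, frame_idx)
  ctx$times <- c(ctx$times, now_min)
  ctx$values <- c(ctx$values, avg)
  ctx$last_seg <- last_seg

  # trailing-window fit, horizon forecast, crossing estimate
  h_frames <- as.integer(cfg$horizon_min / cfg$frame_interval_min)
  fc <- NA_real_; crossing <- NA_real_
  if (length(ctx$values) >= max(10L, n_fit_params("poly2"))) {
    ser <- confluency_series(ctx$frames, ctx$values, cfg$frame_interval_min,
                             time_min = ctx$times)
    fit <- fit_growth_model(ser, cfg$window_frames, "poly2")
    fc <- forecast(fit, now_min + cfg$horizon_min)
    crossing <- time_to_threshold(fit, cfg$threshold, now_min, cfg$horizon_min)
    assign(as.character(frame_idx + h_frames), fc, envir = ctx$pending)
  }
  key <- as.character(frame_idx)
  fc_for_now <- if (exists(key, envir = ctx$pending))
    get(key, envir = ctx$pending) else NA_real_
  ctx$pred_state <- update_variance(ctx$pred_state, avg, fc_for_now)
  variance <- utils::tail(ctx$pred_state$variance_trace, 1)

  upd <- notifier_update(ctx$notif, now_min, frame_idx, avg, crossing, cfg)
  ctx$notif <- upd$state
  for (ev in upd$events) {
    dres <- dispatch(ev, ctx$channels, ctx$notif)
    ctx$notif <- dres$state
    ctx$events <- c(ctx$events, list(ev))
  }

  if (!ctx$header_written) {
    cat(paste(c("frame", "time_min", ctx$fov_ids, "average"), collapse = ","),
        "\n", sep = "", file = ctx$conf_csv)
    cat("frame,time_min,forecast_4h,predicted_crossing_min,variance\n",
        file = ctx$pred_csv)
    ctx$header_written <- TRUE
  }
  cat(paste(c(frame_idx, fmt_num(now_min), fmt_num(vals), fmt_num(avg)),
            collapse = ","), "\n", sep = "", file = ctx$conf_csv, append = TRUE)
  cat(paste(c(frame_idx, fmt_num(now_min), fmt_num(fc), fmt_num(crossing),
              fmt_num(variance)), collapse = ","), "\n", sep = "",
      file = ctx$pred_csv, append = TRUE)
  invisible(NULL)
}

finalize_run <- function(ctx, overlays = TRUE) {
  if (overlays && length(ctx$last_seg %||% list()) > 0) {
    ov_dir <- file.path(ctx$out_dir, "overlays")
    dir.create(ov_dir, showWarnings = FALSE)
    for (fov in names(ctx$last_seg)) {
      ent <- ctx$last_seg[[fov]]
      fr <- read_frame(ent$path)
      render_overlay(fr, ent$mask, file.path(ov_dir, paste0(fov, ".png")))
    }
  }
  list(series = if (length(ctx$frames))
         confluency_series(ctx$frames, ctx$values,
                           ctx$config$frame_interval_min,
                           time_min = ctx$times) else NULL,
       events = ctx$events,
       prediction_state = ctx$pred_state,
       notifier_state = ctx$notif,
       paths = list(confluency = ctx$conf_csv, predictions = ctx$pred_csv,
                    events = ctx$events_log,
                    state = file.path(ctx$out_dir, "state.json"),
                    out_dir = ctx$out_dir))
}

#' Run the monitoring pipeline over a complete on-disk dataset
#'
#' @param input_dir dataset directory (see [pipeline]).
#' @param out_dir output directory for CSVs, logs, state and overlays.
#' @param config a [monitor_config()].
#' @param seg a [segmentation_params()].
#' @param run_id culture-run identifier used in the notifier state.
#' @param channels notification channels; default: one [log_channel()]
#'   writing `events.log`.
#' @param overlays write overlay PNGs for the final time point?
#' @return A list with the averaged [confluency_series], the emitted
#'   `events`, the final `prediction_state` and `notifier_state`, and
#'   output `paths`.
#' @export
run_batch <- function(input_dir, out_dir, config = monitor_config(),
                      seg = segmentation_params(), run_id = "run",
                      channels = NULL, overlays = TRUE) {
  found <- scan_frames(input_dir)
  if (nrow(found) == 0L) stop("no frames found under ", input_dir)
  ctx <- new_pipeline_ctx(input_dir, out_dir, config, seg, run_id, channels)
  ctx$fov_ids <- sort(unique(found$fov))
  for (k in sort(unique(found$frame)))
    process_timepoint(ctx, k, found[found$frame == k, , drop = FALSE])
  if (length(ctx$frames) == 0L) stop("zero processable time points")
  finalize_run(ctx, overlays)
}

#' Watch a directory and process time points as they appear
#'
#' A time point is processed once all expected fields of view are present,
#' or as soon as any later frame has started to appear (the partial time
#' point is then closed out with a warning). The loop exits cleanly after
#' `max_idle_polls` polls with no new complete time point.
#'
#' @inheritParams run_batch
#' @param poll_seconds seconds between directory scans.
#' @param max_idle_polls idle polls before clean shutdown.
#' @return As [run_batch()].
#' @export
run_watch <- function(input_dir, out_dir, config = monitor_config(),
                      seg = segmentation_params(), run_id = "run",
                      channels = NULL, overlays = TRUE,
                      poll_seconds = 1, max_idle_polls = 5L) {
  if (!dir.exists(input_dir)) stop("input directory does not exist")
  ctx <- new_pipeline_ctx(input_dir, out_dir, config, seg, run_id, channels)
  expected_fovs <- NULL
  next_frame <- NULL
  idle <- 0L
  while (idle < max_idle_polls) {
    found <- scan_frames(input_dir)
    progressed <- FALSE
    if (nrow(found) > 0L) {
      if (is.null(expected_fovs)) {
        expected_fovs <- sort(unique(found$fov))
        ctx$fov_ids <- expected_fovs
      }
      if (is.null(next_frame)) next_frame <- min(found$frame)
      repeat {
        rows <- found[found$frame == next_frame, , drop = FALSE]
        later <- any(found$frame > next_frame)
        if (nrow(rows) == 0L && !later) break
        complete <- nrow(rows) >= length(expected_fovs)
        if (!complete && !later) break
        if (nrow(rows) > 0L)
          process_timepoint(ctx, next_frame, rows)
        next_frame <- next_frame + 1L
        progressed <- TRUE
      }
    }
    if (progressed) idle <- 0L
    else {
      idle <- idle + 1L
      Sys.sleep(poll_seconds)
    }
  }
  if (length(ctx$frames) == 0L) stop("no processable time points appeared")
  finalize_run(ctx, overlays)
}

#' Render a static run report
#'
#' Plots the measured average confluency, the horizon-ahead forecast
#' trace, the threshold line and event markers from a pipeline output
#' directory, with a thumbnail strip of the final-time-point overlays when
#' present — a static stand-in for a live monitoring dashboard.
#'
#' @param out_dir a [run_batch()] / [run_watch()] output directory.
#' @param path output PNG (default `report.png` inside `out_dir`).
#' @param threshold confluency threshold to draw (default 0.5).
#' @return Invisibly, a list with the parsed `confluency` and
#'   `predictions` tables and the `events` lines used for the markers.
#' @export
report <- function(out_dir, path = file.path(out_dir, "report.png"),
                   threshold = 0.5) {
  conf_csv <- file.path(out_dir, "confluency.csv")
  if (!file.exists(conf_csv)) stop("missing confluency.csv in ", out_dir)
  conf <- utils::read.csv(conf_csv)
  pred_csv <- file.path(out_dir, "predictions.csv")
  pred <- if (file.exists(pred_csv)) utils::read.csv(pred_csv) else NULL
  ev_file <- file.path(out_dir, "events.log")
  ev <- if (file.exists(ev_file)) readLines(ev_file, warn = FALSE) else character(0)
  ev <- ev[nzchar(ev)]
  ev_t <- as.numeric(sub(".*\\tt_min=([0-9.eE+-]+)\\t.*", "\\1", ev))
  ev_kind <- sub("^[^\t]*\t([A-Z_]+)\t.*", "\\1", ev)

  ov_dir <- file.path(out_dir, "overlays")
  ov_files <- if (dir.exists(ov_dir))
    sort(list.files(ov_dir, pattern = "\\.png$", full.names = TRUE))
  else character(0)

  grDevices::png(path, width = 900, height = if (length(ov_files)) 700 else 450)
  on.exit(grDevices::dev.off())
  if (length(ov_files)) graphics::layout(matrix(1:2, 2, 1), heights = c(2, 1))
  graphics::par(mar = c(4, 4, 2, 1))
  plot(conf$time_min, conf$average, type = "l", col = "red", lwd = 2,
       ylim = c(0, 1), xlab = "time (min)", ylab = "confluency",
       main = "Measured and predicted confluency")
  if (!is.null(pred))
    graphics::lines(pred$time_min + 0 * pred$forecast_4h, pred$forecast_4h,
                    col = "forestgreen", lwd = 1.5)
  graphics::abline(h = threshold, col = "blue", lty = 2)
  if (length(ev_t))
    graphics::abline(v = ev_t, col = ifelse(ev_kind == "PRE_ALERT",
                                            "orange", "purple"), lty = 3)
  graphics::legend("topleft", bty = "n",
                   legend = c("measured", "forecast (+4 h)", "threshold"),
                   col = c("red", "forestgreen", "blue"),
                   lty = c(1, 1, 2), lwd = c(2, 1.5, 1))
  if (length(ov_files)) {
    graphics::par(mar = c(1, 1, 2, 1))
    plot(0, 0, type = "n", xlim = c(0, length(ov_files)), ylim = c(0, 1),
         axes = FALSE, xlab = "", ylab = "",
         main = "Final time point (overlays)")
    for (i in seq_along(ov_files)) {
      img <- png::readPNG(ov_files[i])
      graphics::rasterImage(img, i - 1 + 0.05, 0.05, i - 0.05, 0.95)
    }
  }
  invisible(list(confluency = conf, predictions = pred, events = ev,
                 path = path))
}
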