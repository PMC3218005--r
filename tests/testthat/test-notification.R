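feed_series <- function(series, config, state = notifier_state("t"),
                        window_frames = config$window_frames) {
  events <- list()
  for (i in seq_len(nrow(series))) {
    now <- series$time_min[i]
    crossing <- NA_real_
    if (i >= 10) {
      fit <- fit_growth_model(series[1:i, ], window_frames)
      crossing <- time_to_threshold(fit, config$threshold, now,
                                    config$horizon_min)
    }
    upd <- notifier_update(state, now, series$frame[i], series$value[i],
                           crossing, config)
    state <- upd$state
    events <- c(events, upd$events)
  }
  list(state = state, events = events)
}

test_that("a decreasing culture never triggers events", {
  k <- 0:299
  s <- confluency_series(k, clip01(0.45 - 0.0005 * k))
  out <- feed_series(s, monitor_config(min_frames = 50))
  expect_length(out$events, 0)
})

test_that("warm-up suppresses the advance alert even with an imminent crossing", {
  cfg <- monitor_config(min_frames = 200)
  st <- notifier_state("warm")
  # frame 150 (< 200) with a predicted crossing only 60 min away
  upd <- notifier_update(st, 750, 150L, 0.45, 810, cfg)
  expect_length(upd$events, 0)
  # same situation past warm-up fires
  upd2 <- notifier_update(upd$state, 1000, 200L, 0.45, 1060, cfg)
  expect_equal(vapply(upd2$events, `[[`, "", "kind"), "PRE_ALERT")
})

test_that("noise-free quadratic run: one advance alert 235-240 min before crossing", {
  cfg <- monitor_config()
  s <- quadratic_series(n_frames = 700)
  out <- feed_series(s, cfg)
  kinds <- vapply(out$events, `[[`, "", "kind")
  expect_equal(sum(kinds == "PRE_ALERT"), 1)
  expect_equal(sum(kinds == "THRESHOLD_REACHED"), 1)
  pre <- out$events[[which(kinds == "PRE_ALERT")]]
  thr <- out$events[[which(kinds == "THRESHOLD_REACHED")]]
  # reminder fires at the first measured frame at/above threshold
  first_cross <- s$time_min[which(s$value >= 0.5)[1]]
  expect_equal(thr$time_min, first_cross)
  lead <- thr$time_min - pre$time_min
  expect_gte(lead, 235)
  expect_lte(lead, 240)
  expect_lte(pre$time_min, thr$time_min)
})

test_that("events are at-most-once, including across persisted restarts", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "state.json")
  cfg <- monitor_config(min_frames = 10)
  st <- notifier_state("run7", path = path)
  upd <- notifier_update(st, 100, 20L, 0.55, 100, cfg)
  expect_length(upd$events, 2)  # alert + reminder in the same update

  # restart from disk: re-feeding later frames emits nothing new
  st2 <- notifier_state("ignored", path = path)
  expect_equal(st2$run_id, "run7")
  upd2 <- notifier_update(st2, 105, 21L, 0.60, 105, cfg)
  expect_length(upd2$events, 0)

  expect_error(notifier_update(upd2$state, 90, 15L, 0.5, NA, cfg),
               "out-of-order")
})

test_that("dispatch logs events, isolates channel failures, refuses duplicates", {
  dir <- withr::local_tempdir()
  log_path <- file.path(dir, "events.log")
  st <- notifier_state("runX")
  upd <- notifier_update(st, 1000, 200L, 0.51, NA, monitor_config())
  ev <- upd$events[[1]]

  bad <- list(name = "broken", send = function(event) stop("relay down"))
  res <- dispatch(ev, list(log_channel(log_path), bad), upd$state)
  expect_equal(res$report$ok, c(TRUE, FALSE))
  expect_match(res$report$detail[2], "relay down")
  lines <- readLines(log_path)
  expect_length(lines, 1)
  expect_match(lines, "THRESHOLD_REACHED")

  # same event again: refused for every channel, nothing appended
  res2 <- dispatch(ev, list(log_channel(log_path)), res$state)
  expect_false(any(res2$report$ok))
  expect_match(res2$report$detail, "duplicate")
  expect_length(readLines(log_path), 1)
})

test_that("the smtp stub refuses to send unless explicitly configured", {
  st <- notifier_state("runY")
  upd <- notifier_update(st, 1000, 200L, 0.51, NA, monitor_config())
  res <- dispatch(upd$events[[1]], list(smtp_channel()))
  expect_false(res$report$ok)
  expect_match(res$report$detail, "not configured")
})

test_that("monitor configuration is validated", {
  expect_error(monitor_config(threshold = 0), "threshold")
  expect_error(monitor_config(threshold = 1.2), "threshold")
  expect_error(monitor_config(horizon_min = 242), "multiple")
  st <- notifier_state("z")
  expect_error(notifier_update(st, 0, 0L, 1.5, NA, monitor_config()),
               "avg_confluency")
})
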