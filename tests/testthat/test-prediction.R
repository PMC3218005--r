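test_that("noise-free quadratic data are recovered to 1e-9", {
  s <- quadratic_series(n_frames = 400)
  fit <- fit_growth_model(s, window_frames = 300)
  expect_equal(unname(coef(fit)), c(0.05, 1e-4, 1e-6), tolerance = 1e-9)
  expect_lt(fit$in_window_rmse, 1e-12)
})

test_that("a constant series fits as a flat quadratic", {
  s <- confluency_series(0:99, rep(0.3, 100))
  fit <- fit_growth_model(s, window_frames = 300)
  cf <- unname(coef(fit))
  expect_lt(abs(cf[1] - 0.3), 1e-12)
  expect_lt(abs(cf[2]), 1e-12)
  expect_lt(abs(cf[3]), 1e-12)
})

test_that("noisy coefficients fall within 3 SE of truth (normal-equations oracle)", {
  s <- quadratic_series(n_frames = 400, noise_sigma = 0.005, seed = 1)
  fit <- fit_growth_model(s, window_frames = 300)
  # independent closed-form least squares with standard errors, raw frame basis
  win <- s[101:400, ]
  X <- cbind(1, win$frame, win$frame^2)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% win$value
  sigma2 <- sum((win$value - X %*% beta)^2) / (nrow(X) - 3)
  se <- sqrt(diag(XtX_inv) * sigma2)
  truth <- c(0.05, 1e-4, 1e-6)
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-6)
  expect_true(all(abs(coef(fit) - truth) < 3 * se))
})

test_that("window shorter than requested is clipped; too-short series errors", {
  s <- quadratic_series(n_frames = 50)
  fit <- fit_growth_model(s, window_frames = 300)
  expect_equal(fit$n, 50)
  expect_error(fit_growth_model(confluency_series(0:1, c(0.1, 0.2))),
               "cannot identify")
  bad <- confluency_series(0:19, rep(0.2, 20))
  bad$value[3] <- NaN
  expect_error(fit_growth_model(bad), "non-finite")
})

test_that("forecasts evaluate the fitted family", {
  flat <- fit_growth_model(confluency_series(0:49, rep(0.3, 50)))
  expect_equal(forecast(flat, 1000), 0.3, tolerance = 1e-9)
  expect_equal(forecast(flat, 123456), 0.3, tolerance = 1e-9)

  # linear growth 0.001/frame, value 0.3 at the window end, +48 frames
  k <- 0:48
  lin <- confluency_series(k, 0.252 + 0.001 * k)
  fitl <- fit_growth_model(lin, family = "poly1")
  expect_equal(forecast(fitl, (48 + 48) * 5), 0.348, tolerance = 1e-9)

  # quadratic fixture matches an independent Horner evaluation of coef()
  s <- quadratic_series(n_frames = 350, noise_sigma = 0.003, seed = 8)
  fit <- fit_growth_model(s)
  cf <- coef(fit)
  horner <- function(kk) (cf[3] * kk + cf[2]) * kk + cf[1]
  for (kk in c(360, 400, 500))
    expect_equal(forecast(fit, kk * 5, clip = FALSE), unname(horner(kk)),
                 tolerance = 1e-12)
})

test_that("forecast clipping applies to reporting only", {
  k <- 0:49
  s <- confluency_series(k, clip01(0.9 + 0.001 * k))
  fit <- fit_growth_model(s, family = "poly1")
  expect_equal(forecast(fit, 5000), 1)
  expect_gt(forecast(fit, 5000, clip = FALSE), 1)
})

test_that("threshold crossing matches algebra on linear fits", {
  # reaches 0.5 at now + 200 frames = now + 1000 min: outside a 240-min horizon
  k <- 0:99
  s1 <- confluency_series(k, 0.401 + 0.0005 * k)  # 0.4505 at k=99, +0.0005/frame
  fit1 <- fit_growth_model(s1, family = "poly1")
  now <- max(s1$time_min)
  expect_true(is.na(time_to_threshold(fit1, 0.5, now, 240)))

  # 0.46 now, 0.001/frame: crossing in 40 frames = 200 min
  s2 <- confluency_series(k, 0.361 + 0.001 * k)
  fit2 <- fit_growth_model(s2, family = "poly1")
  now2 <- max(s2$time_min)
  expect_equal(time_to_threshold(fit2, 0.5, now2, 240), now2 + 200,
               tolerance = 1e-6)

  # already at threshold: immediate event path
  s3 <- confluency_series(k, clip01(0.51 + 0 * k))
  fit3 <- fit_growth_model(s3, family = "poly1")
  expect_equal(time_to_threshold(fit3, 0.5, max(s3$time_min), 240),
               max(s3$time_min))
  expect_error(time_to_threshold(fit2, 0), "threshold")
})

test_that("closed-form crossings agree with a dense 0.1-min scan", {
  for (seed in 1:6) {
    s <- quadratic_series(n_frames = 500, a2 = 2e-6, a1 = 5e-5, c0 = 0.2,
                          noise_sigma = 0.004, seed = seed)
    fit <- fit_growth_model(s)
    now <- max(s$time_min)
    t_cf <- time_to_threshold(fit, 0.5, now, 240)
    grid <- seq(now, now + 240, by = 0.1)
    hit <- grid[forecast(fit, grid, clip = FALSE) >= 0.5]
    t_scan <- if (length(hit)) hit[1] else NA_real_
    if (is.na(t_scan)) expect_true(is.na(t_cf))
    else expect_lt(abs(t_cf - t_scan), 0.1)
  }
})

test_that("crossing time is consistent for strictly increasing fits", {
  # clean crossing at frame 500, series ends at frame 479 (value ~0.477)
  s <- quadratic_series(n_frames = 480, a2 = 1e-6, a1 = 1e-4, c0 = 0.2)
  fit <- fit_growth_model(s)
  now <- max(s$time_min)
  t_star <- time_to_threshold(fit, 0.5, now, 240)
  expect_false(is.na(t_star))
  expect_gte(forecast(fit, t_star, clip = FALSE), 0.5 - 1e-8)
  expect_lt(forecast(fit, t_star - 1, clip = FALSE), 0.5)
})

test_that("variance trace follows the trailing sample variance of errors", {
  st <- prediction_state(var_window = 48)
  for (i in 1:60) st <- update_variance(st, 0.4, 0.4)
  expect_true(all(st$variance_trace[-1] == 0))

  # alternating +/- e errors: mean 0, sample variance 48 e^2 / 47 when full
  e <- 0.01
  st2 <- prediction_state(var_window = 48)
  for (i in 1:100) st2 <- update_variance(st2, 0.4, 0.4 + e * (-1)^i)
  expect_equal(tail(st2$variance_trace, 1), 48 * e^2 / 47, tolerance = 1e-12)

  # warm-up NA records are kept out of the error history
  st3 <- prediction_state()
  st3 <- update_variance(st3, 0.3, NA)
  expect_length(st3$error, 0)
  expect_true(is.na(st3$variance_trace[1]))
})

test_that("noise-free in-family forecasts leave a ~zero variance trace", {
  s <- quadratic_series(n_frames = 260)
  rf <- rolling_forecast(s, window_frames = 100, horizon_min = 240)
  st <- prediction_state(48)
  for (i in seq_len(nrow(rf)))
    st <- update_variance(st, rf$observed[i], rf$forecast[i])
  expect_lt(max(st$variance_trace[-1]), 1e-12)
})

test_that("rmse matches a naive element-wise loop", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(0, 2)), sqrt(0.5))
  set.seed(2)
  a <- runif(101); b <- runif(101)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(rmse(a, b), sqrt(acc / length(a)), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "equal")
})

test_that("model comparison honours model-class containment on noiseless data", {
  s <- quadratic_series(n_frames = 400)
  tab <- compare_models(s, window_frames = 300, warmup_points = 100)
  r <- setNames(tab$forecast_rmse, tab$family)
  expect_lt(r[["poly2"]], 1e-9)
  expect_lt(r[["poly3"]], 1e-9)
  expect_gt(r[["poly1"]], r[["poly2"]])
  expect_gt(r[["poly1"]], r[["poly3"]])
})

test_that("logarithmic-truth data rank the logarithmic family first", {
  k <- 0:399
  v <- clip01(0.1 + 0.08 * log(k + 1))
  s <- confluency_series(k, v)
  tab <- compare_models(s, window_frames = 300, warmup_points = 100)
  expect_equal(tab$family[1], "logarithmic")
})

test_that("exponential fitting rejects non-positive data without failing others", {
  k <- 0:299
  v <- c(rep(0, 10), clip01(0.001 * (k[-(1:10)])))
  s <- confluency_series(k, v)
  tab <- compare_models(s, families = c("poly2", "exponential"),
                        window_frames = 100, warmup_points = 50)
  expect_true(is.na(tab$forecast_rmse[tab$family == "exponential"]))
  expect_false(is.na(tab$forecast_rmse[tab$family == "poly2"]))
})

test_that("stride-1 subsampling is the identity; noiseless strides stay exact", {
  s <- quadratic_series(n_frames = 400)
  r1 <- subsample_compare(s, stride = 1, warmup_frames = 100)
  expect_identical(r1$rmse_full, r1$rmse_strided)
  r6 <- subsample_compare(s, stride = 6, warmup_frames = 100)
  expect_lt(r6$rmse_full, 1e-9)
  expect_lt(r6$rmse_strided, 1e-9)
  expect_error(subsample_compare(s, stride = 1000), "larger")
})
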