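GROWTH_FAMILIES <- c("poly1", "poly2", "poly3", "logarithmic", "exponential")

n_fit_params <- function(family) {
  switch(family, poly1 = 2L, poly2 = 3L, poly3 = 4L,
         logarithmic = 2L, exponential = 2L,
         stop("unknown model family: '", family, "'"))
}

# expand poly coefficients b (ascending, in s = (k - m)/h) to the k scale
poly_unscale <- function(b, m, h) {
  lin <- c(-m / h, 1 / h)
  out <- numeric(length(b)); out[1] <- b[1]
  pw <- 1
  for (j in seq_len(length(b) - 1L)) {
    pw <- convolve_poly(pw, lin)
    out[seq_along(pw)] <- out[seq_along(pw)] + b[j + 1L] * pw
  }
  out
}

convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Fit a growth model to the trailing window of a confluency series
#'
#' The monitor's model: a least-squares fit of the chosen family on the
#' trailing `window_frames` observations. Polynomial families are fitted on
#' centred-and-scaled frame indices for conditioning and the coefficients
#' mapped back, so reported coefficients are on the raw frame-index scale
#' (value per frame, per frame squared, ...). The default, a 2nd-order
#' polynomial over the last 300 frames (25 h at 5-min sampling), is the
#' configuration that best forecast C2C12 myoblast growth among the five
#' families offered here.
#'
#' Families: `poly1`/`poly2`/`poly3` are polynomials in the frame index
#' `k`; `logarithmic` is `alpha * log(k - k0 + 1) + beta` with `k0` the
#' first frame of the window; `exponential` is `alpha * exp(beta * k)`
#' (requires positive observations; fitted by Gauss-Newton from a
#' log-linear start).
#'
#' @param series a [confluency_series] (or coercible data frame / numeric
#'   vector).
#' @param window_frames number of trailing observations to fit (clipped to
#'   the available length).
#' @param family one of `"poly1"`, `"poly2"`, `"poly3"`, `"logarithmic"`,
#'   `"exponential"`.
#' @return An object of class `growth_fit`; see [forecast()],
#'   [time_to_threshold()], and the `print`, `coef`, `summary`, `predict`,
#'   `residuals`, `plot` methods.
#' @examples
#' s <- generate_growth_series(synthetic_growth_params(n_frames = 400))
#' fit <- fit_growth_model(s)
#' coef(fit)
#' forecast(fit, t_future_min = max(s$time_min) + 240)
#' @export
fit_growth_model <- function(series, window_frames = 300L,
                             family = "poly2") {
  series <- as_confluency_series(series)
  family <- match.arg(family, GROWTH_FAMILIES)
  if (any(!is.finite(series$value))) stop("non-finite values in series")
  n <- nrow(series)
  w <- min(as.integer(window_frames), n)
  npar <- n_fit_params(family)
  if (w < npar)
    stop(sprintf("window of %d point(s) cannot identify %d '%s' parameters",
                 w, npar, family))
  win <- series[(n - w + 1L):n, , drop = FALSE]
  k <- as.numeric(win$frame)
  y <- win$value
  m <- mean(k)
  h <- max(stats::sd(k), 1e-9)
  s <- (k - m) / h
  interval <- series_interval(series)

  if (family %in% c("poly1", "poly2", "poly3")) {
    deg <- npar - 1L
    X <- stats::poly(s, degree = deg, raw = TRUE)
    X <- cbind(1, X)
    fit <- stats::lm.fit(X, y)
    b <- unname(fit$coefficients)
    coefs <- poly_unscale(b, m, h)
    names(coefs) <- paste0("k^", seq_along(coefs) - 1L)
    fitted <- drop(X %*% b)
    pars <- list(b_scaled = b)
  } else if (family == "logarithmic") {
    k0 <- k[1]
    z <- log(k - k0 + 1)
    fit <- stats::lm.fit(cbind(1, z), y)
    beta <- unname(fit$coefficients[1]); alpha <- unname(fit$coefficients[2])
    coefs <- c(alpha = alpha, beta = beta, k0 = k0)
    fitted <- beta + alpha * z
    pars <- list(alpha = alpha, beta = beta, k0 = k0)
  } else {  # exponential
    if (any(y <= 0))
      stop("exponential family requires strictly positive observations")
    lf <- stats::lm.fit(cbind(1, s), log(y))
    A0 <- exp(unname(lf$coefficients[1])); B0 <- unname(lf$coefficients[2])
    df <- data.frame(s = s, y = y)
    nl <- tryCatch(
      stats::nls(y ~ A * exp(B * s), data = df,
                 start = list(A = A0, B = B0),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl); A <- unname(cf["A"]); B <- unname(cf["B"])
    } else { A <- A0; B <- B0 }
    # alpha * exp(beta k) with s = (k - m)/h
    beta <- B / h
    alpha <- A * exp(-B * m / h)
    coefs <- c(alpha = alpha, beta = beta)
    fitted <- A * exp(B * s)
    pars <- list(alpha = alpha, beta = beta)
  }

  if (any(!is.finite(coefs))) stop("non-finite fitted coefficients")
  structure(
    list(family = family, coefficients = coefs, pars = pars,
         scale = list(center = m, scale = h),
         window = c(first_frame = win$frame[1], last_frame = win$frame[w]),
         time_origin_min = win$time_min[1],
         frame_interval_min = interval,
         window_end_min = win$time_min[w],
         in_window_rmse = sqrt(mean((y - fitted)^2)),
         n = w,
         window_data = win),
    class = "growth_fit")
}

# unclipped family evaluation at (vector of) frame index k
eval_fit_frames <- function(fit, k) {
  switch(fit$family,
    poly1 = , poly2 = , poly3 = {
      s <- (k - fit$scale$center) / fit$scale$scale
      b <- fit$pars$b_scaled
      out <- rep(b[length(b)], length(k))
      for (j in rev(seq_len(length(b) - 1L))) out <- out * s + b[j]
      out
    },
    logarithmic = {
      z <- log(pmax(k - fit$pars$k0 + 1, .Machine$double.eps))
      fit$pars$beta + fit$pars$alpha * z
    },
    exponential = fit$pars$alpha * exp(fit$pars$beta * k))
}

min_to_frame <- function(fit, t_min) t_min / fit$frame_interval_min

#' Forecast confluency at a future time
#'
#' Evaluates the fitted family at `t_future_min`. Values are clipped to
#' `[0, 1]` for reporting (a confluency cannot leave that range); pass
#' `clip = FALSE` for the raw model value, which is what the
#' threshold-crossing root finder uses.
#'
#' @param fit a [fit_growth_model()] object.
#' @param t_future_min time(s) in minutes (>= end of the fit window for a
#'   true forecast; earlier times evaluate the fit in-window).
#' @param clip clip the result to `[0, 1]`?
#' @return Forecast confluency value(s).
#' @export
forecast <- function(fit, t_future_min, clip = TRUE) {
  stopifnot(inherits(fit, "growth_fit"))
  v <- eval_fit_frames(fit, min_to_frame(fit, t_future_min))
  if (clip) clip01(v) else v
}

#' Earliest predicted threshold-crossing time
#'
#' Finds the earliest `t` in `(now, now + horizon]` at which the fitted
#' (unclipped) curve reaches the confluency threshold. If the curve is
#' already at or above threshold at `now`, `now` is returned (the immediate
#' threshold event path). Polynomial families are solved by closed-form
#' root finding on the scaled basis; other families (or a degenerate root
#' solve) fall back to a 1-min grid scan refined by bisection.
#'
#' @param fit a [fit_growth_model()] object.
#' @param threshold confluency threshold in `(0, 1]` (default 0.5).
#' @param now_min current time, minutes; defaults to the fit window end.
#' @param horizon_min look-ahead horizon, minutes (default 240 = 4 h).
#' @return Crossing time in minutes, or `NA_real_` when the curve does not
#'   reach the threshold within the horizon.
#' @export
time_to_threshold <- function(fit, threshold = 0.5,
                              now_min = fit$window_end_min,
                              horizon_min = 240) {
  stopifnot(inherits(fit, "growth_fit"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  f <- function(t) forecast(fit, t, clip = FALSE)
  if (f(now_min) >= threshold) return(now_min)
  t_hi <- now_min + horizon_min

  if (fit$family %in% c("poly1", "poly2", "poly3")) {
    b <- fit$pars$b_scaled
    b[1] <- b[1] - threshold
    if (any(b[-1] != 0)) {
      rt <- polyroot(b)
      rt <- Re(rt[abs(Im(rt)) < 1e-8])
      k_rt <- fit$scale$center + fit$scale$scale * rt
      t_rt <- k_rt * fit$frame_interval_min
      t_rt <- sort(t_rt[t_rt > now_min + 1e-9 & t_rt <= t_hi + 1e-9])
      for (t0 in t_rt)
        if (f(t0) >= threshold - 1e-8) return(min(t0, t_hi))
      return(NA_real_)
    }
  }
  # grid scan at 1-min resolution, bisection refine
  grid <- seq(now_min, t_hi, by = 1)
  if (grid[length(grid)] < t_hi) grid <- c(grid, t_hi)
  vals <- f(grid)
  idx <- which(vals >= threshold)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  lo <- grid[i - 1L]; hi <- grid[i]
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid) >= threshold) hi <- mid else lo <- mid
  }
  hi
}

#' Root-mean-square error between two series
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0L)
    stop("series must have equal, positive length")
  sqrt(mean((predicted - observed)^2))
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> family %s, window frames %d..%d (%d points)\n",
              x$family, x$window["first_frame"], x$window["last_frame"], x$n))
  cat("  coefficients (frame-index scale):\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("  in-window RMSE: %.3g\n", x$in_window_rmse))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
summary.growth_fit <- function(object, ...) {
  end <- object$window_end_min
  cat(sprintf("Growth fit (%s) on %d frames ending at t = %g min\n",
              object$family, object$n, end))
  print(signif(object$coefficients, 6))
  cat(sprintf("in-window RMSE %.3g; forecast at +240 min: %.4f\n",
              object$in_window_rmse, forecast(object, end + 240)))
  crossing <- time_to_threshold(object)
  if (is.na(crossing)) cat("no 0.5 crossing predicted within 4 h\n")
  else cat(sprintf("predicted 0.5 crossing at t = %.1f min (in %.1f min)\n",
                   crossing, crossing - end))
  invisible(object)
}

#' @export
predict.growth_fit <- function(object, t_future_min = NULL, ...) {
  if (is.null(t_future_min))
    t_future_min <- object$window_data$time_min
  forecast(object, t_future_min)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$window_data$value -
    eval_fit_frames(object, as.numeric(object$window_data$frame))
}

#' @export
plot.growth_fit <- function(x, horizon_min = 240, ...) {
  wd <- x$window_data
  t_ext <- seq(wd$time_min[1], x$window_end_min + horizon_min, length.out = 200)
  plot(wd$time_min, wd$value, pch = 16, cex = 0.4, col = "grey40",
       xlim = range(t_ext), ylim = c(0, 1),
       xlab = "time (min)", ylab = "confluency", ...)
  graphics::lines(t_ext, forecast(x, t_ext), col = "forestgreen", lwd = 2)
  graphics::abline(v = x$window_end_min, lty = 3)
  invisible(x)
}
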