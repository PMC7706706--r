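#' Broken-DNA fraction from PFGE signals
#'
#' DSB frequency in a lane: broken-molecule signal divided by the sum of
#' parental and broken signals.
#'
#' @param broken_signal,parental_signal non-negative signals (vectorized).
#' @return fraction in `[0, 1)`.
#' @export
dsb_fraction <- function(broken_signal, parental_signal) {
  if (any(broken_signal < 0) || any(parental_signal < 0))
    stop("signals must be >= 0")
  if (any(broken_signal + parental_signal == 0))
    stop("broken and parental signals are both zero")
  broken_signal / (parental_signal + broken_signal)
}

#' Poisson correction of an observed broken fraction
#'
#' Converts the observed fraction of broken molecules into the mean number of
#' breaks per chromatid under a Poisson model of break counts: the observed
#' intact class has probability `1 - f = exp(-lambda)`, so
#' `lambda = -log(1 - f)`. This corrects for chromatids carrying multiple
#' DSBs, which a gel scores only once. Always `lambda >= f`, with equality in
#' the small-f limit.
#'
#' @param f observed broken fraction(s) in `[0, 1)`, or percent if
#'   `percent = TRUE`.
#' @param percent treat `f` as percent and return percent-equivalent mean.
#' @return corrected mean breaks per chromatid (same scale as input).
#' @export
poisson_correct <- function(f, percent = FALSE) {
  x <- if (percent) f / 100 else f
  if (any(x < 0) || any(x >= 1))
    stop("broken fraction must be in [0, 1)")
  lam <- -log1p(-x)
  if (percent) lam * 100 else lam
}

lognormal_peak <- function(x, a, b, c, d) {
  a + b * exp(-(log(x + 1) - c)^2 / d^2)
}

# bounded multi-start least squares for the log-normal peak curve with fixed a
fit_lognormal_bcd <- function(t, y, a, d_starts = c(0.3, 0.6, 1.2)) {
  rss_fun <- function(p) {
    r <- y - lognormal_peak(t, a, p[1], p[2], p[3])
    sum(r * r)
  }
  b0 <- max(y) - a
  c0 <- log(t[which.max(y)] + 1)
  lower <- c(0, -2, 1e-3)
  upper <- c(max(10 * (max(y) - min(y)), 1), log(max(t) + 1) + 2, 10)
  starts <- c(lapply(d_starts, function(d0) c(max(b0, 1e-3), c0, d0)),
              list(c(max(b0 / 2, 1e-3), max(c0 - 0.3, -1), 0.6)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, rss_fun, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("log-normal fit failed to converge from all starts")
  # polish the winner with a derivative-free pass; L-BFGS-B line searches
  # can terminate abnormally on nearly-flat residual surfaces
  pol <- tryCatch(
    stats::optim(best$par, rss_fun, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) {
    pol$par <- pmin(pmax(pol$par, lower), upper)
    best <- pol
  }
  list(b = best$par[1], c = best$par[2], d = best$par[3],
       rss = best$value, converged = best$convergence == 0)
}

#' Fit the log-normal DSB-timing curve to a time course
#'
#' Fits `y = a + b * exp(-(log(x + 1) - c)^2 / d^2)` to a DSB-frequency time
#' course by bounded multi-start least squares, with the background `a` fixed
#' to the observed 0-h value. The curve peaks at `x = exp(c) - 1`, reported
#' as `peak_time_h`.
#'
#' @param tc a [time_course()] with at least 4 points including t = 0.
#' @return An object of class `dsb_kinetic_fit` with components `a`, `b`,
#'   `c`, `d`, `peak_time_h`, `rss`, `converged`, `data`.
#' @export
fit_dsb_kinetics <- function(tc) {
  t <- tc$time_h; y <- tc$value
  if (length(t) < 4)
    stop("need at least 4 time points")
  if (t[1] != 0)
    stop("time course must include a 0-h point (background)")
  a <- y[1]
  fit <- fit_lognormal_bcd(t, y, a)
  structure(
    list(a = a, b = fit$b, c = fit$c, d = fit$d,
         peak_time_h = exp(fit$c) - 1, rss = fit$rss,
         converged = fit$converged, data = tc,
         label = attr(tc, "label")),
    class = "dsb_kinetic_fit")
}

#' @export
print.dsb_kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "Log-normal DSB kinetics fit%s\n",
    if (!is.na(x$label)) paste0(" ('", x$label, "')") else ""))
  cat(sprintf("  a = %.4g (fixed), b = %.4g, c = %.4g, d = %.4g\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("  peak time = %.3g h, RSS = %.4g%s\n", x$peak_time_h, x$rss,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' @export
coef.dsb_kinetic_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, d = object$d)
}

#' @export
predict.dsb_kinetic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_h
       else if (is.data.frame(newdata)) newdata$time_h
       else as.numeric(newdata)
  lognormal_peak(t, object$a, object$b, object$c, object$d)
}

#' @export
residuals.dsb_kinetic_fit <- function(object, ...) {
  object$data$value - predict(object)
}

#' @export
summary.dsb_kinetic_fit <- function(object, ...) {
  out <- c(coef(object), peak_time_h = object$peak_time_h,
           rss = object$rss)
  class(object) <- NULL
  print.dsb_kinetic_fit(structure(object, class = "dsb_kinetic_fit"))
  invisible(out)
}

#' @export
plot.dsb_kinetic_fit <- function(x, ...) {
  graphics::plot(x$data$time_h, x$data$value, xlab = "Time (h)",
                 ylab = "DSB frequency", pch = 16, ...)
  tt <- seq(min(x$data$time_h), max(x$data$time_h), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Time-averaged signal (area under the curve)
#'
#' Trapezoidal integral of the observed points over time; units are
#' value-units times hours (e.g. percent-hours). Optionally subtracts the 0-h
#' background from every point first.
#'
#' @param tc a [time_course()] with at least 2 points.
#' @param subtract_background subtract the first (earliest) value.
#' @return numeric area under the curve.
#' @export
time_averaged_dsbs <- function(tc, subtract_background = FALSE) {
  t <- tc$time_h; y <- tc$value
  if (length(t) < 2)
    stop("need at least 2 time points")
  if (subtract_background) y <- y - y[1]
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

logistic_curve <- function(t, L, k, t0) L / (1 + exp(-k * (t - t0)))

# least-squares 3-parameter logistic, direction +1 (rising) or -1 (falling)
fit_logistic <- function(t, y, direction = 1) {
  rss_fun <- function(p) {
    r <- y - logistic_curve(t, p[1], direction * p[2], p[3])
    sum(r * r)
  }
  L0 <- max(y)
  half <- L0 / 2
  t0_guess <- t[which.min(abs(y - half))]
  lower <- c(1e-9, 1e-3, min(t) - 2)
  upper <- c(10 * max(L0, 1e-6), 50, max(t) + 2)
  best <- NULL
  for (k0 in c(1, 2, 4, 8)) {
    fit <- tryCatch(
      stats::optim(c(max(L0, 1e-6), k0, t0_guess), rss_fun,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("logistic fit failed to converge from all starts")
  pol <- tryCatch(
    stats::optim(best$par, rss_fun, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) {
    pol$par <- pmin(pmax(pol$par, lower), upper)
    best <- pol
  }
  list(L = best$par[1], k = direction * best$par[2], t0 = best$par[3],
       rss = best$value)
}

#' Association/dissociation timing from a ChIP time course
#'
#' Three-stage estimate of a protein's chromosomal binding window from a
#' unimodal ChIP-qPCR profile:
#'
#' 1. fit the same log-normal peak curve as [fit_dsb_kinetics()] to locate
#'    the peak time;
#' 2. fit a 3-parameter saturating logistic `L / (1 + exp(-k (t - t0)))` to
#'    the observed points at `t <= peak` (the peak-time sample itself
#'    included); the association time is where the logistic reaches half its
#'    fitted maximum (`t0`);
#' 3. mirror with a decreasing logistic on `t >= peak` for the dissociation
#'    time. Binding duration is dissociation minus association time.
#'
#' Half-maximum times are defined on the fitted plateau `L`, so the estimates
#' are invariant under amplitude scaling of the series.
#'
#' @param tc a [time_course()] with at least 6 points.
#' @return An object of class `chip_binding_fit` with components
#'   `peak_time_h`, `t_assoc_h`, `t_dissoc_h`, `duration_h`, the stage fits,
#'   and the input data.
#' @export
fit_chip_kinetics <- function(tc) {
  t <- tc$time_h; y <- tc$value
  if (length(t) < 6)
    stop("need at least 6 time points")
  a <- y[1]
  stage1 <- fit_lognormal_bcd(t, y, a)
  peak <- exp(stage1$c) - 1
  peak <- min(max(peak, min(t)), max(t))

  rise_i <- which(t <= peak)
  if (length(rise_i) < 3)
    stop("fewer than 3 points on the rising slope")
  fall_i <- which(t >= peak)
  if (length(fall_i) < 3)
    stop("fewer than 3 points on the falling slope")

  rise <- fit_logistic(t[rise_i], y[rise_i], direction = 1)
  fall <- fit_logistic(t[fall_i], y[fall_i], direction = -1)
  t_assoc <- min(rise$t0, peak)
  t_dissoc <- max(fall$t0, peak)
  structure(
    list(peak_time_h = peak, t_assoc_h = t_assoc, t_dissoc_h = t_dissoc,
         duration_h = t_dissoc - t_assoc,
         peak_fit = stage1, rise_fit = rise, fall_fit = fall,
         data = tc, label = attr(tc, "label")),
    class = "chip_binding_fit")
}

#' @export
print.chip_binding_fit <- function(x, ...) {
  cat(sprintf(
    "ChIP binding window%s\n",
    if (!is.na(x$label)) paste0(" ('", x$label, "')") else ""))
  cat(sprintf("  peak %.3g h; association %.3g h; dissociation %.3g h\n",
              x$peak_time_h, x$t_assoc_h, x$t_dissoc_h))
  cat(sprintf("  binding duration %.3g h\n", x$duration_h))
  invisible(x)
}

#' @export
coef.chip_binding_fit <- function(object, ...) {
  c(peak_time_h = object$peak_time_h, t_assoc_h = object$t_assoc_h,
    t_dissoc_h = object$t_dissoc_h, duration_h = object$duration_h)
}

#' @export
plot.chip_binding_fit <- function(x, ...) {
  graphics::plot(x$data$time_h, x$data$value, xlab = "Time (h)",
                 ylab = "ChIP signal (% of input)", pch = 16, ...)
  graphics::abline(v = c(x$t_assoc_h, x$t_dissoc_h), lty = 2)
  graphics::abline(v = x$peak_time_h, lty = 3)
  invisible(x)
}
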