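#' Single-component cosinor fit
#'
#' Least-squares fit of a cosine with a fixed trial period to a series:
#' \deqn{y(t) = M + \beta \cos(\omega t) + \gamma \sin(\omega t), \quad
#'       \omega = 2\pi/\tau}
#' reparameterised as \eqn{y(t) = M + A \cos(\omega t + \phi)} with mesor
#' \eqn{M} (rhythm-adjusted mean), amplitude \eqn{A = \sqrt{\beta^2 +
#' \gamma^2} \ge 0} (half the peak-to-trough extent) and acrophase
#' \eqn{\phi} in degrees, reported in \eqn{(-360, 0]} where 360° equals
#' the trial period and 0° is the series start; the fitted cosine peaks at
#' \eqn{t = -\phi\tau/360} hours.
#'
#' The rhythm's contribution to variance is the percent rhythm
#' \eqn{PR = SS_{model}/SS_{total}}, and the zero-amplitude test uses
#' \eqn{F = (SS_{model}/2) / (SS_{resid}/(n-3))} on \eqn{(2, n-3)}
#' degrees of freedom: under the null of no rhythm at this trial period
#' the p value is uniform, so rejection at \eqn{p < \alpha} detects a
#' rhythm at type-I level \eqn{\alpha}.
#'
#' The design does not require equidistant sampling, so phase-subset
#' series are acceptable. Trial periods resonant with the sampling grid
#' make the cosine/sine regressors collinear (or zero); such degenerate
#' designs are detected by a condition-number threshold of 1e8 and
#' rejected.
#'
#' @param x a [corrected_series()], or a numeric vector of values (then
#'   `times` must be given).
#' @param period trial period \eqn{\tau} in hours; must be at least twice
#'   the median sampling interval.
#' @param times sampling times in hours (only when `x` is numeric).
#' @return an object of class `cosinor` with components `coefficients`
#'   (named `mesor`, `amplitude`, `acrophase`), `beta`, `gamma`, `period`,
#'   `n`, `times`, `y`, `fitted.values`, `residuals`, `ss` (`total`,
#'   `model`, `resid`), `percent_rhythm`, `statistic`, `df`, `p.value`,
#'   `sigma`.
#' @examples
#' t <- seq(0, 23)
#' y <- 5 + 2 * cos(2 * pi * t / 24)
#' fit <- cosinor(y, period = 24, times = t)
#' coef(fit)
#' @seealso [ls_spectrum()], [pool_attenuation()]
#' @export
cosinor <- function(x, period, times = NULL) {
  if (inherits(x, "corrected_series")) {
    y <- x$values
    t <- x$times
  } else {
    y <- as.numeric(x)
    t <- as.numeric(times)
    if (length(t) != length(y)) validation_error("times must match values")
  }
  n <- length(y)
  if (n < 4) validation_error("cosinor needs at least 4 observations")
  med_step <- stats::median(diff(sort(t)))
  if (period < 2 * med_step) {
    validation_error(sprintf(
      "trial period %g h is below twice the sampling interval (%g h)",
      period, med_step))
  }
  omega <- 2 * pi / period
  X <- cbind(mesor = 1, c = cos(omega * t), s = sin(omega * t))
  if (kappa(X, exact = TRUE) > 1e8) {
    stop_circapool(sprintf(
      "degenerate cosinor design at trial period %g h (regressors collinear on this grid)",
      period), "circapool_degenerate_design")
  }
  qx <- qr(X)
  coefs <- qr.coef(qx, y)
  fit <- drop(X %*% coefs)
  res <- y - fit
  beta <- unname(coefs[2]); gamma <- unname(coefs[3])
  A <- sqrt(beta^2 + gamma^2)
  # y = M + A cos(wt + phi) with beta = A cos(phi), gamma = -A sin(phi)
  phi <- canonical_acrophase(atan2(-gamma, beta) * 180 / pi)
  ss_total <- sum((y - mean(y))^2)
  ss_resid <- sum(res^2)
  ss_model <- ss_total - ss_resid
  pr <- if (ss_total > 0) ss_model / ss_total else NA_real_
  df2 <- n - 3
  Fstat <- (ss_model / 2) / (ss_resid / df2)
  pval <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  structure(
    list(coefficients = c(mesor = unname(coefs[1]), amplitude = A,
                          acrophase = phi),
         beta = beta, gamma = gamma, period = period,
         n = n, times = t, y = y,
         fitted.values = fit, residuals = res,
         ss = c(total = ss_total, model = ss_model, resid = ss_resid),
         percent_rhythm = pr,
         statistic = Fstat, df = c(2, df2), p.value = pval,
         sigma = sqrt(ss_resid / df2),
         call = match.call()),
    class = "cosinor"
  )
}

#' Peak time of a fitted cosinor
#'
#' Converts the acrophase to hours after the series start:
#' `-acrophase * period / 360`, in `[0, period)`.
#'
#' @param object a `cosinor` fit.
#' @return peak time in hours.
#' @export
peak_time <- function(object) {
  stopifnot(inherits(object, "cosinor"))
  -object$coefficients[["acrophase"]] * object$period / 360
}

#' @export
print.cosinor <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Cosinor fit, trial period %.4g h (n = %d)\n", x$period, x$n))
  cat(sprintf("  mesor %.4g, amplitude %.4g, acrophase %.1f deg (peak at %.2f h)\n",
              co[["mesor"]], co[["amplitude"]], co[["acrophase"]],
              peak_time(x)))
  cat(sprintf("  percent rhythm %.1f%%; zero-amplitude F(%d,%d) = %.2f, %s\n",
              100 * x$percent_rhythm, x$df[1], x$df[2], x$statistic,
              format_p(x$p.value)))
  invisible(x)
}

#' @export
summary.cosinor <- function(object, ...) {
  structure(list(fit = object), class = "summary.cosinor")
}

#' @export
print.summary.cosinor <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  beta %.4g, gamma %.4g, residual sigma %.4g\n",
              f$beta, f$gamma, f$sigma))
  cat(sprintf("  SS total %.4g = model %.4g + residual %.4g\n",
              f$ss["total"], f$ss["model"], f$ss["resid"]))
  invisible(x)
}

#' @export
coef.cosinor <- function(object, ...) object$coefficients

#' @export
fitted.cosinor <- function(object, ...) object$fitted.values

#' @export
residuals.cosinor <- function(object, ...) object$residuals

#' Evaluate a fitted cosinor at new times
#'
#' @param object a `cosinor` fit.
#' @param newtimes times in hours (defaults to the fitting times).
#' @param ... unused.
#' @return fitted values `M + A cos(2 pi t / period + phi)`.
#' @export
predict.cosinor <- function(object, newtimes = NULL, ...) {
  t <- newtimes %||% object$times
  co <- object$coefficients
  omega <- 2 * pi / object$period
  co[["mesor"]] + co[["amplitude"]] *
    cos(omega * t + co[["acrophase"]] * pi / 180)
}

#' Simulate responses from a fitted cosinor
#'
#' Draws Gaussian residuals around the fitted curve with the residual
#' standard deviation of the fit.
#'
#' @param object a `cosinor` fit.
#' @param nsim number of simulated series.
#' @param seed optional seed passed to [withr::with_seed()].
#' @param ... unused.
#' @return a data.frame with `nsim` columns of simulated values at the
#'   fitting times.
#' @export
simulate.cosinor <- function(object, nsim = 1, seed = NULL, ...) {
  gen <- function() {
    as.data.frame(replicate(
      nsim, object$fitted.values + stats::rnorm(object$n, 0, object$sigma)))
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.cosinor <- function(x, ...) {
  graphics::plot(x$times, x$y, xlab = "time since series start [h]",
                 ylab = "value", main = sprintf("Cosinor, period %.4g h",
                                                x$period), ...)
  tt <- seq(min(x$times), max(x$times), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = x$coefficients[["mesor"]], lty = 3)
  invisible(x)
}

#' Pooling attenuation of a cosine component
#'
#' A value pooled over a window of width `width` hours estimates the
#' window mean, which attenuates a cosine of period `period` by
#' \eqn{\sin(\omega\Delta/2)/(\omega\Delta/2)} (with \eqn{\omega =
#' 2\pi/period}, \eqn{\Delta = } `width`) without shifting its phase when
#' values are anchored at window midpoints. Dividing a fitted amplitude by
#' this factor recovers the amplitude of the underlying continuous
#' component.
#'
#' @param period component period in hours.
#' @param width pooling window width in hours (default 12).
#' @return attenuation factor in (0, 1].
#' @export
pool_attenuation <- function(period, width = 12) {
  x <- pi * width / period
  ifelse(x == 0, 1, sin(x) / x)
}
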