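# autocorrelation and grouped-interval ANOVA
#
# Both operations require the equidistant 12-h grid; phase subsets (24-h
# spaced but offset) are handled by the cosinor/spectrum path instead.

#' Autocorrelation function with confidence bounds
#'
#' Sample autocorrelation \eqn{r_k = \sum_t (x_t - \bar x)(x_{t+k} - \bar
#' x) / \sum_t (x_t - \bar x)^2} (biased n-denominator estimator with the
#' full-series mean — the convention of standard ACF plots), together with
#' the approximate white-noise band \eqn{\pm z_{0.975}/\sqrt{n}}:
#' coefficients outside the band are significant at p < 0.05.
#'
#' @param x a [corrected_series()] on an equidistant grid.
#' @param max_lag maximum lag in sampling steps (default 14).
#' @return an `acf_result`: list with `lags` (0..max_lag), `coefficients`,
#'   `conf_limit`, `n`, `step_h`.
#' @export
acf_series <- function(x, max_lag = 14) {
  stopifnot(inherits(x, "corrected_series"))
  if (!is_full_grid(x)) {
    validation_error("autocorrelation requires a gap-free equidistant series at the pooled resolution")
  }
  n <- length(x$values)
  if (n < max_lag + 3) {
    validation_error(sprintf("need n >= max_lag + 3 (n = %d, max_lag = %d)",
                             n, max_lag))
  }
  if (stats::sd(x$values) == 0) {
    validation_error("zero-variance series: autocorrelation undefined")
  }
  r <- drop(stats::acf(x$values, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf)
  structure(
    list(lags = 0:max_lag, coefficients = r,
         conf_limit = stats::qnorm(0.975) / sqrt(n),
         n = n, step_h = if (n > 1) diff(x$times)[1] else NA_real_),
    class = "acf_result"
  )
}

#' @export
print.acf_result <- function(x, ...) {
  sig <- sum(abs(x$coefficients[-1]) >= x$conf_limit)
  cat(sprintf("ACF to lag %d (steps of %g h), n = %d, conf limit +/- %.3f\n",
              max(x$lags), x$step_h, x$n, x$conf_limit))
  cat(sprintf("  %d of %d nonzero lags significant at p < 0.05\n",
              sig, max(x$lags)))
  invisible(x)
}

#' @export
plot.acf_result <- function(x, ...) {
  graphics::plot(x$lags, x$coefficients, type = "h", ylim = c(-1, 1),
                 xlab = "lag [sampling steps]", ylab = "autocorrelation",
                 ...)
  graphics::abline(h = c(-1, 1) * x$conf_limit, lty = 3)
  graphics::abline(h = 0)
  invisible(x)
}

#' One-way ANOVA over consecutive interval blocks
#'
#' Groups the series into consecutive non-overlapping blocks of
#' `group_len` timepoints (default 8, i.e. 4 days of 12-h intervals) and
#' tests equality of block means by one-way ANOVA. A significant F
#' indicates systematic variation across multi-day blocks, consistent
#' with an about-4-day periodic component (or a trend). A trailing
#' partial block is included when it holds at least 2 values
#' (`partial = "include"`, the default) or dropped (`partial = "drop"`).
#'
#' @param x a [corrected_series()] on an equidistant grid.
#' @param group_len block length in timepoints (default 8).
#' @param partial `"include"` or `"drop"` the trailing partial block.
#' @return an `interval_anova`: list with `F`, `df_between`, `df_within`,
#'   `p`, `group_means`, `group_sizes`, `partial`.
#' @export
interval_anova <- function(x, group_len = 8,
                           partial = c("include", "drop")) {
  stopifnot(inherits(x, "corrected_series"))
  partial <- match.arg(partial)
  if (!is_full_grid(x)) {
    validation_error("interval ANOVA requires a gap-free equidistant series at the pooled resolution")
  }
  n <- length(x$values)
  g <- (seq_len(n) - 1L) %/% group_len + 1L
  tail_size <- n %% group_len
  keep <- rep(TRUE, n)
  if (tail_size > 0 && (partial == "drop" || tail_size < 2)) {
    keep <- g <= n %/% group_len
  }
  v <- x$values[keep]; g <- factor(g[keep])
  if (nlevels(g) < 2) {
    validation_error("interval ANOVA needs at least 2 complete groups")
  }
  a <- stats::anova(stats::lm(v ~ g))
  structure(
    list(F = a[["F value"]][1],
         df_between = a[["Df"]][1], df_within = a[["Df"]][2],
         p = a[["Pr(>F)"]][1],
         group_means = as.numeric(tapply(v, g, mean)),
         group_sizes = as.integer(table(g)),
         partial = partial),
    class = "interval_anova"
  )
}

#' @export
print.interval_anova <- function(x, ...) {
  cat(sprintf("Consecutive-block one-way ANOVA: F(%d,%d) = %.2f, %s\n",
              x$df_between, x$df_within, x$F, format_p(x$p)))
  cat(sprintf("  %d blocks of sizes %s\n", length(x$group_means),
              paste(x$group_sizes, collapse = ",")))
  invisible(x)
}

#' Restrict a series to one phase
#'
#' Keeps only day or only night values, preserving the original time
#' axis. The result is not equidistant in general (offset 24-h spacing),
#' so it is accepted by [cosinor()] and [ls_spectrum()] but rejected by
#' [acf_series()] and [interval_anova()].
#'
#' @param x a [corrected_series()] containing both phases.
#' @param phase `"day"` or `"night"`.
#' @return a [corrected_series()].
#' @export
subset_by_phase <- function(x, phase = c("day", "night")) {
  stopifnot(inherits(x, "corrected_series"))
  phase <- match.arg(phase)
  if (length(unique(x$phases)) < 2) {
    validation_error("series does not contain both phases")
  }
  keep <- x$phases == phase
  if (!any(keep)) validation_error(sprintf("no %s intervals in series", phase))
  corrected_series(x$subject, x$times[keep], x$values[keep],
                   x$phases[keep], x$unit, x$duration)
}
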