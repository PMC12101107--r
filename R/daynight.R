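# day-night pairing and paired statistics
#
# A "24-h period" is a day interval followed immediately by its night
# interval on the 12-h grid. Differences are taken night - day, so the
# dominant day > night pattern yields a negative paired t statistic. An
# inversion is a pair whose night value strictly exceeds its day value.

#' Pair day intervals with the immediately following night interval
#'
#' Walks the alternating series and pairs every day value with the night
#' value that immediately follows it on the grid. A leading night or a
#' trailing day cannot be paired and is counted in `dropped` (it remains
#' part of CV and rhythm analyses, which do not pair). The rule is
#' insensitive to whether the series starts with a day or a night
#' interval.
#'
#' @param x a [corrected_series()] with alternating phases.
#' @return a `day_night_pairs`: list with `pairs` (data.frame
#'   `day_value`, `night_value`, `day_time`), `n_pairs`, `dropped`,
#'   `subject`, `unit`.
#' @export
pair_day_night <- function(x) {
  stopifnot(inherits(x, "corrected_series"))
  n <- length(x$values)
  if (n < 2) validation_error("pairing needs at least 2 intervals")
  if (any(x$phases[-1] == x$phases[-n])) {
    validation_error("phases must alternate for day-night pairing")
  }
  step <- x$duration
  day_idx <- which(x$phases == "day")
  day_idx <- day_idx[day_idx < n &
                       near(x$times[pmin(day_idx + 1, n)] - x$times[day_idx],
                            step)]
  keep <- x$phases[day_idx + 1] == "night"
  day_idx <- day_idx[keep]
  pairs <- data.frame(
    day_value = x$values[day_idx],
    night_value = x$values[day_idx + 1],
    day_time = x$times[day_idx]
  )
  structure(
    list(pairs = pairs, n_pairs = nrow(pairs),
         dropped = n - 2L * nrow(pairs),
         subject = x$subject, unit = x$unit),
    class = "day_night_pairs"
  )
}

#' @export
print.day_night_pairs <- function(x, ...) {
  cat(sprintf("Day-night pairs [%s]: %d pairs, %d unpaired interval(s) dropped\n",
              x$unit, x$n_pairs, x$dropped))
  invisible(x)
}

#' Paired t test on day-night pairs
#'
#' Two-tailed paired Student t test on the differences `night - day`
#' (day-dominant series give negative t), with `n_pairs - 1` degrees of
#' freedom.
#'
#' @param x a [pair_day_night()] result.
#' @return a `daynight_ttest`: list with `t`, `df`, `p`, `mean_diff`
#'   (mean of night - day), `n_pairs`.
#' @export
paired_day_night <- function(x) {
  stopifnot(inherits(x, "day_night_pairs"))
  if (x$n_pairs < 2) validation_error("paired t test needs at least 2 pairs")
  d <- x$pairs$night_value - x$pairs$day_value
  if (stats::sd(d) == 0) {
    validation_error("zero variance of paired differences: t undefined")
  }
  ht <- stats::t.test(x$pairs$night_value, x$pairs$day_value, paired = TRUE)
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_diff = mean(d), n_pairs = x$n_pairs),
    class = "daynight_ttest"
  )
}

#' @export
print.daynight_ttest <- function(x, ...) {
  cat(sprintf("Paired day-night t test: t = %.2f, df = %d, %s (mean night-day = %.4g)\n",
              x$t, x$df, format_p(x$p), x$mean_diff))
  invisible(x)
}

# paper-style p formatting: thresholds only in display, never in storage
format_p <- function(p, alpha_small = 0.01) {
  if (p < alpha_small) sprintf("p < %.2g", alpha_small)
  else sprintf("p = %.2f", p)
}

#' Day-night inversion rate
#'
#' Percentage of 24-h periods in which the night value strictly exceeds
#' the day value (ties count as non-inverted).
#'
#' @param x a [pair_day_night()] result.
#' @return percent of inverted pairs (scalar, full precision; print with
#'   two decimals).
#' @export
inversion_rate <- function(x) {
  stopifnot(inherits(x, "day_night_pairs"))
  if (x$n_pairs < 1) validation_error("no pairs to assess")
  100 * mean(x$pairs$night_value > x$pairs$day_value)
}

#' Pearson correlation between two corrected series
#'
#' Product-moment correlation between two unit regimes of the same
#' underlying series (e.g. creatinine- vs volume-corrected values), with a
#' two-tailed p value from the t transform on n - 2 degrees of freedom.
#'
#' @param x,y [corrected_series()] objects of equal length.
#' @return a `correlation_result`: list with `r`, `p`, `n`, `units`.
#' @export
correction_correlation <- function(x, y) {
  stopifnot(inherits(x, "corrected_series"), inherits(y, "corrected_series"))
  if (length(x$values) != length(y$values)) {
    validation_error("series lengths differ")
  }
  n <- length(x$values)
  if (n < 3) validation_error("correlation needs at least 3 points")
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0) {
    validation_error("zero variance: correlation undefined")
  }
  ht <- stats::cor.test(x$values, y$values, method = "pearson")
  structure(
    list(r = unname(ht$estimate), p = ht$p.value, n = n,
         units = c(x$unit, y$unit)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation (%s vs %s): r = %.2f, %s, n = %d\n",
              x$units[1], x$units[2], x$r, format_p(x$p), x$n))
  invisible(x)
}
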