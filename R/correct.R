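# correction schemes and window aggregation
#
# A pooled 12-h collection yields one averaged concentration per window.
# Two standard corrections remove urine-dilution artefacts:
#   creatinine correction  value = ohdg_conc / creatinine_conc   [ng/mg]
#   volume correction      value = ohdg_conc * volume / 1000 / h [ug/h]
# The uncorrected concentration itself is kept as a third regime so rhythm
# analyses can be run on raw determinations as well.

# excreted biomarker mass per interval, in ng
ohdg_mass_ng <- function(x) x$intervals$ohdg_ng_per_ml * x$intervals$volume_ml

# excreted creatinine mass per interval, in mg
creatinine_mass_mg <- function(x) {
  x$intervals$creatinine_mg_per_ml * x$intervals$volume_ml
}

midpoints <- function(x) x$intervals$start_time + x$intervals$duration / 2

#' Creatinine correction
#'
#' Expresses the biomarker as ng per mg urinary creatinine
#' (`value_i = ohdg_conc_i / creatinine_conc_i`), correcting for urinary
#' flow and glomerular filtration rate. Values are anchored at interval
#' midpoints.
#'
#' @param x a [urine_series()].
#' @return a [corrected_series()] with unit `"ng_per_mg_creatinine"`.
#' @export
correct_creatinine <- function(x) {
  stopifnot(inherits(x, "urine_series"))
  if (any(x$intervals$creatinine_mg_per_ml == 0)) {
    validation_error("creatinine concentration of zero: correction undefined")
  }
  corrected_series(
    x$subject, midpoints(x),
    x$intervals$ohdg_ng_per_ml / x$intervals$creatinine_mg_per_ml,
    x$intervals$phase, "ng_per_mg_creatinine", x$intervals$duration[1]
  )
}

#' Volume correction
#'
#' Expresses the biomarker as µg excreted per hour, averaged over the
#' pooled window (`value_i = ohdg_conc_i * volume_i / 1000 / duration_i`),
#' correcting for hydration status.
#'
#' @param x a [urine_series()].
#' @return a [corrected_series()] with unit `"ug_per_h"`.
#' @export
correct_volume <- function(x) {
  stopifnot(inherits(x, "urine_series"))
  corrected_series(
    x$subject, midpoints(x),
    ohdg_mass_ng(x) / 1000 / x$intervals$duration,
    x$intervals$phase, "ug_per_h", x$intervals$duration[1]
  )
}

#' Uncorrected concentrations as a corrected-series regime
#'
#' Packages the raw biomarker concentrations (ng/mL) as a
#' [corrected_series()] so the rhythm analyses can be applied to the
#' original determinations.
#'
#' @param x a [urine_series()].
#' @return a [corrected_series()] with unit `"raw_ng_per_ml"`.
#' @export
correct_none <- function(x) {
  stopifnot(inherits(x, "urine_series"))
  corrected_series(x$subject, midpoints(x), x$intervals$ohdg_ng_per_ml,
                   x$intervals$phase, "raw_ng_per_ml",
                   x$intervals$duration[1])
}

#' Apply a correction scheme by name
#'
#' @param x a [urine_series()].
#' @param method `"creatinine"`, `"volume"` or `"none"`.
#' @return a [corrected_series()].
#' @export
correct_series <- function(x, method = c("creatinine", "volume", "none")) {
  switch(match.arg(method),
         creatinine = correct_creatinine(x),
         volume     = correct_volume(x),
         none       = correct_none(x))
}

#' Aggregate a pooled series over longer collection windows
#'
#' Pools consecutive 12-h intervals into 12/24/48-h collection windows.
#' The default pools at the physical level, as if the urine had been
#' collected over the longer window: summed biomarker mass over summed
#' creatinine mass (ng/mg regime) or summed mass over window hours (µg/h
#' regime). `method = "mean"` instead averages the per-interval corrected
#' values. Trailing intervals that do not fill a complete window are
#' dropped (a partial pool is not comparable to a complete one).
#'
#' @param x a [urine_series()].
#' @param window window length in hours; one of 12, 24, 48 (any multiple
#'   of the interval duration is accepted).
#' @param unit `"ng_per_mg_creatinine"` or `"ug_per_h"`.
#' @param method `"mass"` (default, physical pooling) or `"mean"`.
#' @return an `aggregated_series`: list with `window`, `unit`, `values`,
#'   `times` (window midpoints), `n_dropped`.
#' @export
aggregate_series <- function(x, window,
                             unit = c("ug_per_h", "ng_per_mg_creatinine"),
                             method = c("mass", "mean")) {
  stopifnot(inherits(x, "urine_series"))
  unit <- match.arg(unit); method <- match.arg(method)
  step <- x$intervals$duration[1]
  if (!near(window %% step, 0) && !near(window %% step, step)) {
    validation_error(sprintf(
      "window (%g h) must be a multiple of the interval duration (%g h)",
      window, step))
  }
  per <- as.integer(round(window / step))
  n_win <- x$n %/% per
  if (n_win < 1) validation_error("series shorter than one aggregation window")
  n_dropped <- x$n - n_win * per
  grp <- rep(seq_len(n_win), each = per)
  idx <- seq_len(n_win * per)
  mass <- ohdg_mass_ng(x)[idx]
  if (method == "mass") {
    values <- if (unit == "ug_per_h") {
      tapply(mass, grp, sum) / 1000 / window
    } else {
      tapply(mass, grp, sum) / tapply(creatinine_mass_mg(x)[idx], grp, sum)
    }
  } else {
    cs <- if (unit == "ug_per_h") correct_volume(x) else correct_creatinine(x)
    values <- tapply(cs$values[idx], grp, mean)
  }
  t0 <- x$intervals$start_time[1]
  structure(
    list(window = window, unit = unit, method = method,
         values = as.numeric(values),
         times = t0 + (seq_len(n_win) - 0.5) * window,
         n_dropped = n_dropped),
    class = "aggregated_series"
  )
}

#' @export
print.aggregated_series <- function(x, ...) {
  cat(sprintf("Aggregated series [%s]: %d windows of %g h (%d intervals dropped)\n",
              x$unit, length(x$values), x$window, x$n_dropped))
  invisible(x)
}

#' Descriptives and coefficients of variation across collection windows
#'
#' Reports mean, SD and range of the 12-h corrected series together with
#' percent coefficients of variation (CV = 100 sd/mean, n-1 denominator)
#' computed separately on day-only and night-only 12-h values and on
#' mass-pooled 24-h and 48-h aggregates. CV reporting requires a corrected
#' unit regime (raw concentrations confound dilution with excretion).
#'
#' @param x a [urine_series()].
#' @param unit `"ng_per_mg_creatinine"` or `"ug_per_h"`.
#' @return a `cv_report`: list with `unit`, `mean`, `sd`, `min`, `max`,
#'   `cv_12h_day`, `cv_12h_night`, `cv_24h`, `cv_48h`.
#' @export
cv_report <- function(x, unit = c("ng_per_mg_creatinine", "ug_per_h")) {
  stopifnot(inherits(x, "urine_series"))
  unit <- match.arg(unit)
  if (x$n < 4) validation_error("cv_report needs at least 4 intervals")
  cs <- if (unit == "ug_per_h") correct_volume(x) else correct_creatinine(x)
  day <- cs$values[cs$phases == "day"]
  night <- cs$values[cs$phases == "night"]
  structure(
    list(unit = unit,
         mean = mean(cs$values), sd = stats::sd(cs$values),
         min = min(cs$values), max = max(cs$values),
         cv_12h_day = cv_percent(day),
         cv_12h_night = cv_percent(night),
         cv_24h = cv_percent(aggregate_series(x, 24, unit)$values),
         cv_48h = cv_percent(aggregate_series(x, 48, unit)$values)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Descriptives [%s]: mean %.2f +/- %.2f, range %.2f-%.2f\n",
              x$unit, x$mean, x$sd, x$min, x$max))
  cat(sprintf("  %% CV  12h day %.2f | 12h night %.2f | 24h %.2f | 48h %.2f\n",
              x$cv_12h_day, x$cv_12h_night, x$cv_24h, x$cv_48h))
  invisible(x)
}
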