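#' Least-squares spectral analysis over harmonic trial periods
#'
#' Fits a single-component [cosinor()] at every trial period
#' \eqn{\tau_k = T/k}, \eqn{k = 1..k_{max}}, where \eqn{T} is a fixed
#' fundamental period (default 720 h = 30 days, chosen as the typical
#' recording length). `k_max` is the largest harmonic whose period still
#' satisfies the Nyquist condition \eqn{\tau_k \ge} `min_period` (twice
#' the sampling interval by default, i.e. 24 h on a 12-h grid). Harmonic
#' trial periods on a complete fundamental span form an orthogonal basis,
#' so percent-rhythm values are near-additive across harmonics.
#'
#' Harmonics whose design is degenerate on the sampling grid (e.g. the
#' 24-h harmonic on a midpoint-anchored 12-h grid, where the cosine
#' regressor vanishes) are dropped and listed in `dropped_harmonics`
#' rather than aborting the spectrum.
#'
#' The peak band is the maximal contiguous run of harmonics containing
#' the percent-rhythm maximum whose PR exceeds half the maximum PR; its
#' summed PR is reported alongside the per-harmonic values.
#'
#' @param x a [corrected_series()] (equidistant or a phase subset).
#' @param fundamental fundamental period \eqn{T} in hours (default 720).
#' @param min_period smallest admissible trial period in hours; default
#'   twice the median sampling interval.
#' @param k_max optional cap on the number of harmonics.
#' @param periods optional explicit vector of trial periods (dense-grid
#'   exploration mode); overrides the harmonic series.
#' @return an `ls_spectrum`: list with `fundamental`, `table` (data.frame
#'   `k`, `period`, `mesor`, `amplitude`, `acrophase`, `percent_rhythm`,
#'   `p_zero_amplitude`), `fits` (list of `cosinor` objects),
#'   `dropped_harmonics`, `peak` (row of the best harmonic), `peak_band`
#'   (`k_lo`, `k_hi`, `period_lo`, `period_hi`, `summed_pr`).
#' @examples
#' t <- seq(6, by = 12, length.out = 60)
#' y <- 10 + 3 * cos(2 * pi * t / 90)
#' sp <- ls_spectrum(corrected_series("s", t, y, rep(c("day", "night"), 30),
#'                                    "ug_per_h"))
#' sp$peak
#' @export
ls_spectrum <- function(x, fundamental = 720, min_period = NULL,
                        k_max = NULL, periods = NULL) {
  stopifnot(inherits(x, "corrected_series"))
  n <- length(x$values)
  if (n < 8) validation_error("spectral analysis needs at least 8 values")
  med_step <- stats::median(diff(x$times))
  min_period <- min_period %||% (2 * med_step)
  if (is.null(periods)) {
    ks <- seq_len(k_max %||% floor(fundamental / min_period))
    periods <- fundamental / ks
    keep <- periods >= min_period - 1e-9
    ks <- ks[keep]; periods <- periods[keep]
  } else {
    ks <- seq_along(periods)
  }
  fits <- vector("list", length(ks))
  dropped <- integer(0)
  for (i in seq_along(ks)) {
    f <- tryCatch(cosinor(x, periods[i]),
                  circapool_degenerate_design = function(e) NULL)
    fits[i] <- list(f)
    if (is.null(f)) dropped <- c(dropped, ks[i])
  }
  ok <- !vapply(fits, is.null, logical(1))
  tab <- data.frame(
    k = ks[ok],
    period = periods[ok],
    mesor = vapply(fits[ok], function(f) f$coefficients[["mesor"]], 0),
    amplitude = vapply(fits[ok], function(f) f$coefficients[["amplitude"]], 0),
    acrophase = vapply(fits[ok], function(f) f$coefficients[["acrophase"]], 0),
    percent_rhythm = vapply(fits[ok], function(f) f$percent_rhythm, 0),
    p_zero_amplitude = vapply(fits[ok], function(f) f$p.value, 0)
  )
  if (nrow(tab) == 0) validation_error("no fittable trial periods")
  imax <- which.max(tab$percent_rhythm)
  half <- tab$percent_rhythm[imax] / 2
  lo <- imax; while (lo > 1 && tab$percent_rhythm[lo - 1] > half &&
                     tab$k[lo - 1] == tab$k[lo] - 1) lo <- lo - 1
  hi <- imax; while (hi < nrow(tab) && tab$percent_rhythm[hi + 1] > half &&
                     tab$k[hi + 1] == tab$k[hi] + 1) hi <- hi + 1
  structure(
    list(fundamental = fundamental, unit = x$unit, n = n,
         table = tab, fits = fits[ok], dropped_harmonics = dropped,
         peak = tab[imax, ],
         peak_band = list(k_lo = tab$k[lo], k_hi = tab$k[hi],
                          period_lo = tab$period[hi],
                          period_hi = tab$period[lo],
                          summed_pr = sum(tab$percent_rhythm[lo:hi]))),
    class = "ls_spectrum"
  )
}

#' @export
print.ls_spectrum <- function(x, ...) {
  cat(sprintf("Least-squares spectrum [%s]: fundamental %g h, %d harmonics (n = %d)\n",
              x$unit, x$fundamental, nrow(x$table), x$n))
  if (length(x$dropped_harmonics)) {
    cat(sprintf("  dropped degenerate harmonic(s): k = %s\n",
                paste(x$dropped_harmonics, collapse = ",")))
  }
  p <- x$peak
  cat(sprintf("  peak: k = %d, period %.1f h, PR %.1f%%, acrophase %.0f deg, %s\n",
              p$k, p$period, 100 * p$percent_rhythm, p$acrophase,
              format_p(p$p_zero_amplitude)))
  b <- x$peak_band
  cat(sprintf("  peak band: periods %.1f-%.1f h (k = %d..%d), summed PR %.1f%%\n",
              b$period_lo, b$period_hi, b$k_lo, b$k_hi, 100 * b$summed_pr))
  invisible(x)
}

#' @export
summary.ls_spectrum <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' @export
plot.ls_spectrum <- function(x, ...) {
  graphics::plot(x$table$period, 100 * x$table$percent_rhythm, type = "h",
                 log = "x", xlab = "trial period [h]",
                 ylab = "percent rhythm [%]",
                 main = "Least-squares spectrum", ...)
  invisible(x)
}
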