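#' Construct a pooled-interval urine series
#'
#' A `urine_series` is an ordered, equidistant, gap-free sequence of pooled
#' urine collections for one subject. Each interval carries its start time
#' (hours since the series start), nominal duration (12 h), a day/night
#' phase label, the collected volume, the biomarker concentration (ng/mL)
#' and the creatinine concentration (mg/mL).
#'
#' Invariants enforced at construction: strictly increasing start times on
#' an exact grid (successive starts differ by one duration), strictly
#' alternating day/night phases, positive durations, volumes and creatinine
#' concentrations, and non-negative biomarker concentrations.
#'
#' @param subject subject identifier (scalar character).
#' @param start_time numeric vector, interval start times in hours since
#'   the series start.
#' @param phase character vector of `"day"` / `"night"` labels.
#' @param volume_ml collected urine volume per interval (mL).
#' @param ohdg_ng_per_ml biomarker (8-OHdG) concentration (ng/mL).
#' @param creatinine_mg_per_ml creatinine concentration (mg/mL).
#' @param duration interval duration in hours (scalar or vector, default 12).
#' @return an object of class `urine_series`.
#' @seealso [read_series()], [correct_creatinine()], [correct_volume()]
#' @export
urine_series <- function(subject, start_time, phase, volume_ml,
                         ohdg_ng_per_ml, creatinine_mg_per_ml,
                         duration = 12) {
  n <- length(start_time)
  duration <- rep_len(duration, n)
  df <- data.frame(
    index = seq_len(n) - 1L,
    start_time = as.numeric(start_time),
    duration = as.numeric(duration),
    phase = as.character(phase),
    volume_ml = as.numeric(volume_ml),
    ohdg_ng_per_ml = as.numeric(ohdg_ng_per_ml),
    creatinine_mg_per_ml = as.numeric(creatinine_mg_per_ml),
    stringsAsFactors = FALSE
  )
  obj <- structure(
    list(subject = as.character(subject)[1], intervals = df, n = n),
    class = "urine_series"
  )
  validate_urine_series(obj)
  obj
}

#' @noRd
validate_urine_series <- function(x) {
  df <- x$intervals
  n <- nrow(df)
  if (n < 1) validation_error("series is empty")
  if (anyNA(df)) validation_error("series contains missing values")
  bad <- which(!df$phase %in% c("day", "night"))
  if (length(bad)) {
    validation_error(sprintf("invalid phase label %s at index %d",
                             dQuote(df$phase[bad[1]]), bad[1] - 1L))
  }
  if (any(df$duration <= 0)) validation_error("duration must be positive")
  bad <- which(df$volume_ml <= 0)
  if (length(bad)) {
    validation_error(sprintf("volume must be positive (index %d: %g)",
                             bad[1] - 1L, df$volume_ml[bad[1]]))
  }
  bad <- which(df$ohdg_ng_per_ml < 0)
  if (length(bad)) {
    validation_error(sprintf("negative biomarker concentration at index %d",
                             bad[1] - 1L))
  }
  bad <- which(df$creatinine_mg_per_ml <= 0)
  if (length(bad)) {
    validation_error(sprintf("creatinine concentration must be positive (index %d)",
                             bad[1] - 1L))
  }
  if (n >= 2) {
    gaps <- diff(df$start_time)
    bad <- which(!near(gaps, df$duration[-n]))
    if (length(bad)) {
      validation_error(sprintf(
        "time grid not equidistant/gap-free at index %d: step %g h, expected %g h",
        bad[1], gaps[bad[1]], df$duration[bad[1]]))
    }
    same <- which(df$phase[-1] == df$phase[-n])
    if (length(same)) {
      validation_error(sprintf("phases do not alternate at index %d", same[1]))
    }
  }
  invisible(x)
}

#' @export
print.urine_series <- function(x, ...) {
  cat(sprintf("Pooled urine series: subject %s, %d intervals of %g h (%g h total)\n",
              x$subject, x$n, x$intervals$duration[1],
              sum(x$intervals$duration)))
  cat(sprintf("  phases: %s ... | volume %g-%g mL | 8-OHdG %.3g-%.3g ng/mL\n",
              paste(utils::head(x$intervals$phase, 4), collapse = ","),
              min(x$intervals$volume_ml), max(x$intervals$volume_ml),
              min(x$intervals$ohdg_ng_per_ml), max(x$intervals$ohdg_ng_per_ml)))
  invisible(x)
}

#' @export
length.urine_series <- function(x) x$n

#' Extract a contiguous sub-series
#'
#' @param x a `urine_series`.
#' @param i contiguous integer indices (1-based).
#' @param ... unused.
#' @return a `urine_series` over the selected intervals.
#' @export
`[.urine_series` <- function(x, i, ...) {
  df <- x$intervals[i, , drop = FALSE]
  urine_series(x$subject, df$start_time, df$phase, df$volume_ml,
               df$ohdg_ng_per_ml, df$creatinine_mg_per_ml, df$duration)
}

# --- corrected series ------------------------------------------------------

#' Units recognised for corrected series
#' @export
CORRECTED_UNITS <- c("raw_ng_per_ml", "ng_per_mg_creatinine", "ug_per_h")

#' Construct a corrected series
#'
#' A `corrected_series` is a numeric series in one unit regime (raw ng/mL,
#' ng per mg creatinine, or µg/h), anchored at interval midpoints, with the
#' day/night phase label of each value. Pooled values estimate the window
#' mean, hence the midpoint anchoring for all time-dependent fitting.
#'
#' @param subject subject identifier.
#' @param times interval midpoints in hours since series start (strictly
#'   increasing).
#' @param values non-negative corrected values.
#' @param phases day/night labels aligned to `values`.
#' @param unit one of `"raw_ng_per_ml"`, `"ng_per_mg_creatinine"`, `"ug_per_h"`.
#' @param duration pooling window width in hours (default 12); kept so the
#'   series can be written back in the start-time CSV dialect.
#' @return an object of class `corrected_series`.
#' @export
corrected_series <- function(subject, times, values, phases, unit,
                             duration = 12) {
  unit <- match.arg(unit, CORRECTED_UNITS)
  times <- as.numeric(times); values <- as.numeric(values)
  phases <- as.character(phases)
  if (length(times) != length(values) || length(values) != length(phases)) {
    validation_error("times, values and phases must have equal length")
  }
  if (anyNA(times) || anyNA(values)) validation_error("missing values in series")
  if (any(values < 0)) validation_error("corrected values must be non-negative")
  if (any(!phases %in% c("day", "night"))) {
    validation_error("phase labels must be 'day' or 'night'")
  }
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    validation_error("times must be strictly increasing")
  }
  structure(
    list(subject = as.character(subject)[1], unit = unit, times = times,
         values = values, phases = phases, duration = duration),
    class = "corrected_series"
  )
}

#' @export
print.corrected_series <- function(x, ...) {
  cat(sprintf("Corrected series [%s]: subject %s, n = %d, t = %g..%g h\n",
              x$unit, x$subject, length(x$values), min(x$times), max(x$times)))
  cat(sprintf("  mean %.4g, sd %.4g, range %.4g-%.4g\n",
              mean(x$values), stats::sd(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.corrected_series <- function(x) length(x$values)

# TRUE when values sit on an equidistant grid
is_equidistant <- function(x) {
  d <- diff(x$times)
  length(d) == 0 || all(near(d, d[1]))
}

# TRUE when the grid is additionally gap-free at the pooled resolution
# (step equals the pooling duration); phase subsets of a 12-h grid are
# equidistant at 24 h but are NOT a full grid, and ACF / interval ANOVA
# reject them
is_full_grid <- function(x) {
  d <- diff(x$times)
  length(d) == 0 || all(near(d, x$duration))
}

# --- CSV I/O ---------------------------------------------------------------

raw_cols <- c("subject", "start_time_h", "phase", "volume_ml",
              "ohdg_ng_per_ml", "creatinine_mg_per_ml")
corrected_cols <- c("subject", "start_time_h", "phase", "value", "unit")

#' Read a pooled-interval series from CSV
#'
#' Two dialects are supported. The *raw* dialect carries the measured
#' quantities (columns `subject, start_time_h, phase, volume_ml,
#' ohdg_ng_per_ml, creatinine_mg_per_ml`) and yields a [urine_series()].
#' The *corrected* dialect carries pre-corrected values (columns
#' `subject, start_time_h, phase, value, unit`) and yields a
#' [corrected_series()]. With `dialect = "auto"` the dialect is detected
#' from the header.
#'
#' @param path CSV file (UTF-8, header row, one row per pooled interval).
#' @param dialect `"auto"`, `"raw"` or `"corrected"`.
#' @param duration interval duration in hours (default 12).
#' @return a `urine_series` or `corrected_series`.
#' @export
read_series <- function(path, dialect = c("auto", "raw", "corrected"),
                        duration = 12) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "auto") {
    dialect <- if ("value" %in% names(df) && "unit" %in% names(df))
      "corrected" else "raw"
  }
  need <- if (dialect == "raw") raw_cols else corrected_cols
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    format_error(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (dialect == "raw") {
    urine_series(df$subject[1], df$start_time_h, df$phase, df$volume_ml,
                 df$ohdg_ng_per_ml, df$creatinine_mg_per_ml, duration)
  } else {
    unit <- unique(df$unit)
    if (length(unit) != 1) format_error("corrected CSV mixes units")
    corrected_series(df$subject[1], df$start_time_h + duration / 2,
                     df$value, df$phase, unit, duration)
  }
}

# full-precision numeric formatting so that write/read round-trips exactly
fmt_num <- function(x) vapply(x, function(v) sprintf("%.17g", v), character(1))

#' Write a series to CSV
#'
#' Writes a [urine_series()] in the raw dialect or a [corrected_series()]
#' in the corrected dialect. Numbers are written at full double precision
#' so a write/read round trip reproduces the values exactly.
#'
#' @param x a `urine_series` or `corrected_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  if (inherits(x, "urine_series")) {
    df <- data.frame(
      subject = x$subject,
      start_time_h = fmt_num(x$intervals$start_time),
      phase = x$intervals$phase,
      volume_ml = fmt_num(x$intervals$volume_ml),
      ohdg_ng_per_ml = fmt_num(x$intervals$ohdg_ng_per_ml),
      creatinine_mg_per_ml = fmt_num(x$intervals$creatinine_mg_per_ml),
      stringsAsFactors = FALSE
    )
  } else if (inherits(x, "corrected_series")) {
    df <- data.frame(
      subject = x$subject,
      start_time_h = fmt_num(x$times - x$duration / 2),
      phase = x$phases,
      value = fmt_num(x$values),
      unit = x$unit,
      stringsAsFactors = FALSE
    )
  } else {
    validation_error("write_series() expects a urine_series or corrected_series")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
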