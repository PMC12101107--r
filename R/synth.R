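# synthetic pooled-urine generator
#
# Phenomenological model of 12-h pooled urinary biomarker excretion. The
# continuous excretion rate (ug/h) is
#
#   r(t) = baseline * phase_mult(t)
#            * [1 + a_c cos(2 pi (t - t_peak)/24)]        (circadian)
#            * [1 + a_s cos(2 pi t/tau_s + phi_s)]        (circasemiseptan)
#
# with phase_mult = day_multiplier during day intervals and 1 at night.
# The mass excreted per pooled window is the analytic integral of r(t)
# over the window (phase_mult is constant within a window because windows
# coincide with phases), then perturbed by multiplicative lognormal noise.
# Collected volume and creatinine concentration are drawn per phase with
# their own means and lognormal noise; the measured concentration is
# mass / volume. Volume-corrected values therefore carry only the mass
# noise, creatinine-corrected values add creatinine noise, and raw
# concentrations add volume noise — which is what lets corrections reveal
# a day-night pattern that raw concentrations bury.

# integral of cos(w t + psi) over [t0, t1]
intcos <- function(w, psi, t0, t1) {
  if (w == 0) return(cos(psi) * (t1 - t0))
  (sin(w * t1 + psi) - sin(w * t0 + psi)) / w
}

#' Ground-truth parameters for the synthetic generator
#'
#' Bundles and validates the generator parameters, recording them as the
#' ground truth attached to every simulated series so parameter-recovery
#' tests can compare estimates against them.
#'
#' Defaults emulate the qualitative structure of month-long 12-h pooled
#' 8-OHdG recordings: a day > night excretion pattern, occasional
#' inverted 24-h periods, higher night-sample variability, roughly flat
#' raw concentrations (the day/night volume ratio matches the day
#' multiplier), and a multiplicative component with a period slightly
#' below 4 days.
#'
#' @param baseline_rate mean excretion rate at night, µg/h.
#' @param day_multiplier multiplicative day-phase excretion factor
#'   (>= 0; > 1 gives the day-dominant pattern).
#' @param circadian_amp,circadian_peak amplitude fraction in `[0, 1)` and
#'   peak clock time (hours) of the 24-h component.
#' @param semiseptan_amp,semiseptan_period,semiseptan_phase amplitude
#'   fraction in `[0, 1)`, period (hours, ~90) and acrophase-convention
#'   phase (degrees in (-360, 0], 0° = series start) of the
#'   circasemiseptan component.
#' @param noise_cv lognormal coefficient of variation of the excreted
#'   mass, day intervals.
#' @param night_noise_ratio multiplier on `noise_cv` for night intervals
#'   (> 1 reproduces the higher night-sample variability).
#' @param volume_day,volume_night mean collected volumes, mL.
#' @param volume_cv lognormal CV of collected volume.
#' @param creatinine_day,creatinine_night mean creatinine concentrations,
#'   mg/mL.
#' @param creatinine_cv lognormal CV of creatinine concentration.
#' @param seed integer seed for exact reproducibility.
#' @return an object of class `urine_truth` (a validated parameter list
#'   with an `inversion_target` entry: the model-implied expected
#'   fraction of inverted creatinine-corrected pairs).
#' @export
urine_truth <- function(baseline_rate = 1.0,
                        day_multiplier = 1.4,
                        circadian_amp = 0.10, circadian_peak = 15,
                        semiseptan_amp = 0.30, semiseptan_period = 90,
                        semiseptan_phase = -282,
                        noise_cv = 0.15, night_noise_ratio = 1.25,
                        volume_day = 700, volume_night = 500,
                        volume_cv = 0.15,
                        creatinine_day = 0.9, creatinine_night = 1.35,
                        creatinine_cv = 0.10,
                        seed = 1L) {
  if (circadian_amp < 0 || circadian_amp >= 1 ||
      semiseptan_amp < 0 || semiseptan_amp >= 1) {
    validation_error("amplitude fractions must lie in [0, 1)")
  }
  if (baseline_rate <= 0 || day_multiplier < 0) {
    validation_error("baseline_rate must be positive, day_multiplier non-negative")
  }
  if (noise_cv < 0 || volume_cv < 0 || creatinine_cv < 0) {
    validation_error("noise CVs must be non-negative")
  }
  if (min(volume_day, volume_night, creatinine_day, creatinine_night) <= 0) {
    validation_error("volume and creatinine means must be positive")
  }
  truth <- list(
    baseline_rate = baseline_rate, day_multiplier = day_multiplier,
    circadian_amp = circadian_amp, circadian_peak = circadian_peak,
    semiseptan_amp = semiseptan_amp, semiseptan_period = semiseptan_period,
    semiseptan_phase = semiseptan_phase,
    noise_cv = noise_cv, night_noise_ratio = night_noise_ratio,
    volume_day = volume_day, volume_night = volume_night,
    volume_cv = volume_cv,
    creatinine_day = creatinine_day, creatinine_night = creatinine_night,
    creatinine_cv = creatinine_cv,
    seed = as.integer(seed)
  )
  # model-implied expected inversion fraction of creatinine-corrected
  # pairs: the log night/day ratio of corrected values is approximately
  # normal; its mean is the deterministic log ratio, its variance the sum
  # of the lognormal log-variances of both members
  s2 <- log(1 + (noise_cv * night_noise_ratio)^2) + log(1 + noise_cv^2) +
    2 * log(1 + volume_cv^2) + 2 * log(1 + creatinine_cv^2)
  mu <- -log(day_multiplier) - log(creatinine_night / creatinine_day) +
    log(volume_day / volume_night)
  truth$inversion_target <- stats::pnorm(mu / sqrt(s2))
  structure(truth, class = "urine_truth")
}

#' @export
print.urine_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: baseline %.3g ug/h, day x%.2f, circadian %.0f%% @%gh,\n",
              x$baseline_rate, x$day_multiplier, 100 * x$circadian_amp,
              x$circadian_peak))
  cat(sprintf("  semiseptan %.0f%% @ %g h phase %.0f deg; noise CV %.0f%% (night x%.2f); seed %d\n",
              100 * x$semiseptan_amp, x$semiseptan_period,
              x$semiseptan_phase, 100 * x$noise_cv, x$night_noise_ratio,
              x$seed))
  cat(sprintf("  expected inversion fraction (creatinine-corrected): %.1f%%\n",
              100 * x$inversion_target))
  invisible(x)
}

# deterministic (noise-free) mass in ng excreted over each pooled window
deterministic_mass_ng <- function(truth, start, duration, phase) {
  w_c <- 2 * pi / 24
  w_s <- 2 * pi / truth$semiseptan_period
  psi_c <- -w_c * truth$circadian_peak
  psi_s <- truth$semiseptan_phase * pi / 180
  a_c <- truth$circadian_amp; a_s <- truth$semiseptan_amp
  mult <- ifelse(phase == "day", truth$day_multiplier, 1)
  end <- start + duration
  mass <- numeric(length(start))
  for (i in seq_along(start)) {
    t0 <- start[i]; t1 <- end[i]
    I <- (t1 - t0) +
      a_c * intcos(w_c, psi_c, t0, t1) +
      a_s * intcos(w_s, psi_s, t0, t1) +
      a_c * a_s / 2 * (intcos(w_c - w_s, psi_c - psi_s, t0, t1) +
                       intcos(w_c + w_s, psi_c + psi_s, t0, t1))
    mass[i] <- truth$baseline_rate * 1000 * mult[i] * I
  }
  mass
}

#' Generate a synthetic pooled-urine series
#'
#' Simulates a [urine_series()] from a [urine_truth()] parameter set:
#' analytic window integrals of the continuous excretion rate give the
#' deterministic mass per interval, multiplicative lognormal noise is
#' applied to mass, volume and creatinine, and concentrations are derived
#' as mass/volume. Fully reproducible from `truth$seed`.
#'
#' @param truth a [urine_truth()].
#' @param n_intervals number of 12-h intervals (>= 8).
#' @param subject subject identifier stored in the series.
#' @param start_phase phase of the first interval (`"day"` or `"night"`).
#' @param start_clock clock time of the first interval start, hours
#'   (default 8, i.e. a day interval running 08:00-20:00).
#' @return a `urine_series` with the `urine_truth` attached as attribute
#'   `"truth"`.
#' @export
generate_series <- function(truth, n_intervals, subject = "synthetic",
                            start_phase = c("day", "night"),
                            start_clock = 8) {
  stopifnot(inherits(truth, "urine_truth"))
  start_phase <- match.arg(start_phase)
  if (n_intervals < 8) validation_error("need at least 8 intervals")
  start <- (seq_len(n_intervals) - 1) * 12
  phase <- rep_len(if (start_phase == "day") c("day", "night")
                   else c("night", "day"), n_intervals)
  det_mass <- deterministic_mass_ng(truth, start, 12, phase)
  is_day <- phase == "day"
  out <- withr::with_seed(truth$seed, {
    cv_mass <- ifelse(is_day, truth$noise_cv,
                      truth$noise_cv * truth$night_noise_ratio)
    mass <- det_mass * vapply(cv_mass, function(cv) rlnorm_cv(1, cv), 0)
    volume <- ifelse(is_day, truth$volume_day, truth$volume_night) *
      rlnorm_cv(n_intervals, truth$volume_cv)
    creat <- ifelse(is_day, truth$creatinine_day, truth$creatinine_night) *
      rlnorm_cv(n_intervals, truth$creatinine_cv)
    list(mass = mass, volume = volume, creat = creat)
  })
  series <- urine_series(subject, start, phase, out$volume,
                         out$mass / out$volume, out$creat)
  attr(series, "truth") <- truth
  attr(series, "start_clock") <- start_clock
  series
}

#' Packaged deterministic study-like fixtures
#'
#' Deterministic synthetic series mimicking the structure of the two
#' month-long recordings the pipeline is designed for: `subject1_like`
#' has 63 12-h intervals (31.5 days), `subject2_like` has 55 (27.5
#' days). Both start with a day interval, show a day > night pattern in
#' corrected values with occasional inversions, higher night variability,
#' and a multiplicative component with a period slightly below 4 days.
#' The same series ship as CSV fixtures (raw dialect, with a JSON truth
#' sidecar) under `inst/extdata/`; filenames are prefixed `synthetic_`
#' because the series are simulated, not measured.
#'
#' @param profile `"subject1_like"` or `"subject2_like"`.
#' @return a `urine_series` with attached `urine_truth`.
#' @export
make_fixture <- function(profile = c("subject1_like", "subject2_like")) {
  profile <- match.arg(profile)
  if (profile == "subject1_like") {
    truth <- urine_truth(seed = 20041207L)
    generate_series(truth, 63, subject = "subject1_like")
  } else {
    truth <- urine_truth(baseline_rate = 0.8, semiseptan_amp = 0.2,
                         semiseptan_phase = -276, noise_cv = 0.20,
                         seed = 20060713L)
    generate_series(truth, 55, subject = "subject2_like")
  }
}
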