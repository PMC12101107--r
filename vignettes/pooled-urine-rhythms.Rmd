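---
title: "Methods: rhythm analysis of pooled-interval urine series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm analysis of pooled-interval urine series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circapool)
```

This vignette is the package's account of its statistical methods: the
data model, the correction schemes, the day-night statistics, the
cosinor/spectral machinery, the synthetic generator, and the numerical
and design choices behind each — including the choices that were
genuinely open and why they were settled the way they were.

## The data model

The unit of observation is a *pooled interval*: one urine collection
accumulating all voids over a nominally 12-h window, assayed once for
the biomarker (ng/mL) and once for creatinine (mg/mL), with the total
volume recorded. A subject's recording is an ordered, equidistant,
gap-free sequence of such intervals with strictly alternating day
(~08:00–20:00) and night (~20:00–08:00) phases, typically 50–65
intervals (4–5 weeks). Validation enforces all of this at construction
and reports the offending index on failure; analyses never have to
defend against half-formed inputs.

The internal time axis is *hours since the first interval's start*.
This matches the spectral phase convention (0° = series start) and
avoids calendar arithmetic entirely; calendar anchoring is metadata a
caller can keep alongside. Corrected values are anchored at **interval
midpoints**: a pooled value estimates the window mean, and for any
cosine component the window mean equals the midpoint value times a
known attenuation (below), so midpoint anchoring is the choice that
keeps phase estimation unbiased.

Two CSV dialects are read (`read_series()`): a *raw* dialect carrying
the measured quantities and a *corrected* dialect carrying one value
per interval in a declared unit. Deposited datasets in this field ship
in either form, so the reader auto-detects by column names with an
override flag. Numbers are written back at full double precision
(`%.17g`), making write→read round trips exact.

## Correction schemes

Raw concentrations confound excretion with hydration. Two standard
corrections are provided, each a `corrected_series` regime:

* **creatinine correction** `value = ohdg_conc / creatinine_conc`
  (ng/mg): normalises by a co-excreted internal standard, correcting
  urinary flow and glomerular filtration;
* **volume correction** `value = ohdg_conc × volume / 1000 / duration`
  (µg/h): the average excretion rate over the pool.

The uncorrected concentration is kept as a third regime
(`correct_none()`) because rhythms can differ materially between raw
and corrected series — the pipeline always analyses all three.

**Window aggregation** (`aggregate_series()`) pools 12-h intervals into
24-h or 48-h collection windows *at the mass level* — summed biomarker
mass over summed creatinine mass, or summed mass over window hours —
i.e. exactly what a longer physical collection would have measured. The
alternative (mean of the per-interval corrected values) is exposed via
`method = "mean"`; the two differ in the ng/mg regime, where mass
pooling is a creatinine-weighted mean. Trailing intervals that do not
fill a window are dropped, not padded: a partial pool is not comparable
to a complete one. In the µg/h regime total excreted mass over complete
windows is conserved by construction.

`cv_report()` gives the descriptives and percent coefficients of
variation (100·sd/mean, n−1 denominator) for day-only and night-only
12-h values and for the 24-h and 48-h mass-pooled aggregates. CV
reporting requires a corrected unit; on raw concentrations a CV mixes
dilution noise with excretion and is not comparable across windows.

## Day-night statistics

`pair_day_night()` pairs each day interval with the night interval that
*immediately follows* it on the grid; a leading night or trailing day
is unpairable and is counted as dropped (63 alternating intervals
starting with day give 31 pairs, 55 give 27). The rule was defined to
be insensitive to which phase starts the series. Unpaired intervals
stay in the CV and rhythm analyses, which do not pair.

Differences are taken **night − day**, so the common day-dominant
pattern yields a negative paired t — the sign convention used in
day-night biomarker reporting. The paired t statistic and its
two-tailed p (df = pairs − 1) come from `stats::t.test`; an
*inversion* is a pair with night strictly above day (ties are
non-inversions, since an inversion means strictly "higher at night"),
reported in percent. Pearson correlation between the two corrected
regimes (`correction_correlation()`) quantifies whether the correction
choice matters for ranking. p values are stored at full precision;
threshold-style formatting (`p < 0.01`) happens only in printing. No
multiplicity correction is applied; the text report counts the tests it
shows so a reader can apply one.

## Autocorrelation and block ANOVA

`acf_series()` uses the biased (n-denominator, full-series mean)
autocorrelation estimator — the convention under which the
±1.96/√n white-noise band drawn on standard ACF plots is calibrated —
with the band at `qnorm(0.975)/sqrt(n)`. The band itself is an
asymptotic convention, not an exact test.

`interval_anova()` groups the series into consecutive blocks of 8
timepoints (4 days) and runs one-way ANOVA on block means. With 63
intervals the tail block has 7 points; whether to keep it is
consequential, so both policies exist: the default includes a trailing
block with ≥ 2 values, `partial = "drop"` discards it.

Both operations require the full 12-h grid. A phase subset
(`subset_by_phase()`) is equidistant at 24 h but is *not* the grid the
lag unit and the blocking assume, so ACF and ANOVA reject it; the
cosinor and spectrum, which use actual times, accept it.

## Cosinor and least-squares spectrum

The cosinor model, its parameters and the zero-amplitude test are
described in the README. Numerical notes:

* The fit is solved by QR on the explicit design `[1, cos ωt, sin ωt]`,
  not by a general modelling wrapper, keeping the estimator
  self-contained and fast enough for thousands of refits in
  simulations.
* **Degeneracy.** On a midpoint-anchored 12-h grid the 24-h cosine
  column is identically zero (t = 6 + 12k ⇒ cos(2πt/24) = 0): the trial
  period equals the Nyquist limit and the phase is unidentifiable.
  Designs with condition number above 1e8 are rejected with a
  dedicated error class.
* **Acrophase canonicalisation.** φ is mapped to (−360°, 0°]; values
  within 1e-9° of the branch cut snap to 0 so a noiseless peak at the
  series start reports exactly 0 rather than −360.
* Trial periods below twice the sampling interval are refused outright.

`ls_spectrum()` evaluates the cosinor at the harmonic series
τ_k = T/k of a fundamental T. The default T = 720 h (30 days, a
typical recording length) is used for all series lengths — harmonics of
a common fundamental keep multi-subject spectra comparable — and is
configurable per series. Harmonics are preferred over a dense period
grid because on a (near-)complete fundamental span they form an
orthogonal basis: percent-rhythm values are then near-additive and sum
to at most 1 (a Parseval-style bound the tests assert). A dense-grid
mode exists via the `periods` argument for exploration. The
Nyquist-degenerate harmonic (k = 30 under the defaults) is dropped and
recorded in `dropped_harmonics` rather than aborting the spectrum: the
degeneracy is structural to the grid, not a property of the data, and
propagating it would make every default spectrum fail. The *peak band*
is the maximal contiguous run of harmonics around the PR maximum with
PR above half the maximum; both the single best harmonic and the band's
summed PR are reported, since "variance explained by the peak" is
ambiguous between the two.

**Pooling attenuation.** A pooled value is a window mean, which
multiplies a cosine of period τ by sin(ωΔ/2)/(ωΔ/2) (Δ = 12 h) and
shifts nothing at midpoint anchoring — at τ = 90 h the factor is
`r round(pool_attenuation(90), 4)`. Fitting is done on pooled values
as-is, matching how such data are analysed in practice;
`pool_attenuation()` is exposed so recovery tests (and users) can
de-attenuate amplitudes.

## The synthetic generator

`generate_series()` simulates the full measurement chain from a
recorded ground truth (`urine_truth`): a continuous excretion rate

    r(t) = baseline × phase_mult(t) × [1 + a_c cos(2π(t − t_peak)/24)]
                                    × [1 + a_s cos(2πt/τ_s + φ_s)]

is integrated *analytically* over each 12-h window (the phase
multiplier is constant within a window because windows coincide with
phases), giving the deterministic excreted mass; multiplicative
lognormal noise (unit mean) is then applied to mass, collected volume
and creatinine concentration, and the measured concentration is
mass/volume. Lognormal noise was chosen over additive Gaussian because
concentrations are positive and variability in this field is reported
as CV, which is scale-free under a multiplicative model.

The noise routing reproduces *why correction matters*: volume-corrected
values carry only mass noise, creatinine-corrected values add
creatinine noise, raw concentrations add volume noise. The day-night
difference is modelled both as a phase multiplier and as a 24-h cosine;
volume and creatinine have their own day/night means, and with the
default day/night volume ratio equal to the day multiplier the raw
concentrations are approximately flat — so corrected series show a
clear day > night pattern that the raw series buries, the qualitative
situation the pipeline is designed to detect. Night pools get an
inflated noise CV (ratio 1.25), reproducing the higher night-sample
variability of real recordings *in expectation* — any single
realisation can order the two CVs either way.

Defaults (baseline 1 µg/h; day multiplier 1.4; circadian amplitude 0.10
peaking at 15:00; circasemiseptan amplitude 0.30 at 90 h, phase −282°;
noise CV 15%; volumes 700/500 mL day/night; creatinine 0.9/1.35 mg/mL)
were fixed once as a realistic profile for month-long 12-h pooled
8-OHdG recordings: the semiseptan amplitude puts the ~90-h component at
roughly half to two-thirds of raw-series variance, and the implied
inversion fraction of corrected pairs is ~10%, both in the range
reported for such data. The truth object also records the
model-implied expected inversion fraction (a closed-form normal
approximation on the log scale) for trend checks.

`make_fixture()` packages two deterministic profiles (63 and 55
intervals, seeds fixed at construction) that also ship as plain CSV
with JSON truth sidecars; filenames carry a `synthetic_` prefix because
the series are simulated, not measured.

**What the generator does not emulate:** assay cross-reactivity and
measurement rounding, missing or irregular collections, behavioural
covariates (activity, diet, sleep disruption), non-stationary baselines
and between-day phase drift. Passing tests therefore demonstrate
correctness of the *methods* under the stated generative model, not
robustness to every pathology of real recordings.

## Validation design and problem sizes

The test suite checks every estimator against an independent route:
direct-formula transcriptions for t, r, CV and ACF; a brute-force grid
search over (M, A, φ) at 0.5° and 1e-3 amplitude resolution for the
cosinor (50 random series in the acceptance suite); `stats::lm` as an
independent linear-model cross-check; numerical `integrate()` against
the generator's analytic window integrals. Calibration of the
zero-amplitude test is checked at n = 63 over 2000 white-noise
simulations (acceptance) and 500 (unit suite, with a uniformity check
on p); white-noise ACF band coverage over 200 simulated series;
inversion-trend and CV-ordering checks over 30–40 seeds per condition.
These sizes keep the default suite in the tens of seconds while leaving
Monte-Carlo margins far wider than the assertion tolerances.

Spectral parameter recovery is measured over 100 simulated subjects at
n = 63 and noise CV 15% (semiseptan component isolated, so the recovery
target is unambiguous): success requires the peak within one harmonic
step, phase within 5° and de-attenuated amplitude within 10%. A useful
calibration note: at these settings the amplitude standard error is
σ√(2/n) ≈ 0.027 and the phase standard error ≈ 5.3°, i.e. the 5°/10%
box is of the same order as one standard error — so per-seed success
substantially below 1 is the statistically expected outcome, and the
measured success rate (reported by `scripts/acceptance.R`) should be
read against that yardstick rather than as a software defect. Raising
the success rate to ~90% would require either a much larger amplitude
(percent rhythm ≈ 0.9, unrealistic for these data) or longer series.

## Known limitations

* Single-component fits only: no simultaneous multi-harmonic cosinor,
  no population-mean cosinor across subjects, no gliding windows.
* The ±1.96/√n ACF band and the zero-amplitude F test assume
  approximate normality/stationarity of residuals.
* No handling of missing intervals: the data model deliberately rejects
  gapped series rather than imputing.
* Parametric day-night testing only (no Wilcoxon alternative), and no
  multiple-testing correction beyond reporting the test count.
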