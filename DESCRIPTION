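Package: circapool
Title: Rhythm Analysis of Pooled-Interval Urinary Biomarker Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chronobiological analysis of consecutive 12-h pooled
    urine collections of a biomarker such as 8-hydroxy-2'-deoxyguanosine
    (8-OHdG). Provides a validated data model for equidistant day/night
    pooled-interval series, creatinine and urine-volume correction schemes,
    window aggregation with coefficient-of-variation reporting, day-night
    pairing with paired t tests and inversion rates, autocorrelation with
    confidence bounds, grouped-interval one-way ANOVA, single-component
    cosinor fitting with the zero-amplitude test, least-squares spectral
    analysis over a harmonic series of trial periods, a synthetic-data
    generator with recorded ground truth for end-to-end validation, and a
    reproducible per-subject analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
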