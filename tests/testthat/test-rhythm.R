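# autocorrelation, grouped-interval ANOVA, cosinor, spectrum

test_that("autocorrelation matches the biased-estimator formula", {
  # lag 0 is 1 by definition
  cs <- random_corrected(30, 2)
  a <- acf_series(cs, max_lag = 10)
  expect_equal(a$coefficients[1], 1)

  # alternating +-1 of length 8: lag-1 coefficient is -7/8
  alt <- mk_corrected(rep(c(2, 0), 4))  # shifted to stay non-negative
  expect_equal(acf_series(alt, max_lag = 2)$coefficients[2], -7 / 8)

  # every lag agrees with the direct summation oracle
  for (k in 1:10) {
    expect_equal(a$coefficients[k + 1], oracle_acf(cs$values, k),
                 tolerance = 1e-12)
  }
  expect_equal(a$conf_limit, qnorm(0.975) / sqrt(30))

  expect_error(acf_series(mk_corrected(rep(5, 20))), "variance",
               class = "circapool_validation_error")
  expect_error(acf_series(random_corrected(10, 1), max_lag = 14),
               class = "circapool_validation_error")
})

test_that("white-noise ACF stays inside the confidence band about 95% of the time", {
  hits <- withr::with_seed(42, {
    vapply(1:200, function(i) {
      cs <- mk_corrected(exp(rnorm(63, 2, 0.3)))
      a <- acf_series(cs, max_lag = 14)
      mean(abs(a$coefficients[-1]) < a$conf_limit)
    }, 0)
  })
  # the band is asymptotic and lags are correlated; coverage near 0.95
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("interval ANOVA reproduces hand-computed F and handles partial blocks", {
  # groups {1,2} and {3,4}: SSB = 4, SSW = 1, F = 8 on (1, 2) df
  cs <- mk_corrected(c(1, 2, 3, 4))
  r <- interval_anova(cs, group_len = 2)
  expect_equal(r$F, 8)
  expect_equal(c(r$df_between, r$df_within), c(1, 2))
  expect_equal(r$group_means, c(1.5, 3.5))

  # equal group means with within-group spread: F = 0
  r0 <- interval_anova(mk_corrected(c(1, 3, 3, 1)), group_len = 2)
  expect_equal(r0$F, 0)

  # 63 points, blocks of 8: trailing block of 7 included by default
  cs63 <- random_corrected(63, 9)
  ri <- interval_anova(cs63)
  expect_equal(sum(ri$group_sizes), 63)
  expect_equal(length(ri$group_means), 8)
  rd <- interval_anova(cs63, partial = "drop")
  expect_equal(sum(rd$group_sizes), 56)
  expect_equal(rd$df_between, 6)

  expect_error(interval_anova(random_corrected(9, 1), group_len = 8),
               "groups", class = "circapool_validation_error")
  # phase subsets are rejected (offset 24-h spacing is not the full grid)
  expect_error(interval_anova(subset_by_phase(cs63, "night")),
               class = "circapool_validation_error")
})

test_that("cosinor recovers a noiseless cosine exactly", {
  t <- 0:23
  y <- 5 + 2 * cos(2 * pi * t / 24)
  fit <- cosinor(y, period = 24, times = t)
  expect_equal(coef(fit), c(mesor = 5, amplitude = 2, acrophase = 0),
               tolerance = 1e-9)
  expect_equal(fit$percent_rhythm, 1, tolerance = 1e-9)

  # peak at quarter period: acrophase -90 degrees
  tm <- 6 + 12 * (0:20)
  y2 <- 3 + cos(2 * pi * (tm - 22.5) / 90)
  fit2 <- cosinor(y2, period = 90, times = tm)
  expect_equal(coef(fit2)[["acrophase"]], -90, tolerance = 1e-9)
  expect_equal(peak_time(fit2), 22.5, tolerance = 1e-9)
})

test_that("fitted curve attains mesor + amplitude at the peak time", {
  for (seed in 1:10) {
    cs <- random_corrected(25, seed)
    fit <- cosinor(cs, period = 90)
    peak_val <- predict(fit, peak_time(fit))
    expect_equal(peak_val,
                 coef(fit)[["mesor"]] + coef(fit)[["amplitude"]],
                 tolerance = 1e-9)
    # and it is the maximum over one period
    tt <- seq(0, fit$period, length.out = 10000)
    expect_gte(peak_val + 1e-9, max(predict(fit, tt)))
  }
})

test_that("cosinor agrees with an independent linear-model fit", {
  cs <- random_corrected(40, 4)
  w <- 2 * pi / 100
  lmfit <- lm(cs$values ~ cos(w * cs$times) + sin(w * cs$times))
  fit <- cosinor(cs, period = 100)
  expect_equal(fit$coefficients[["mesor"]], unname(coef(lmfit)[1]),
               tolerance = 1e-10)
  expect_equal(fit$coefficients[["amplitude"]],
               sqrt(sum(coef(lmfit)[2:3]^2)), tolerance = 1e-10)
  expect_equal(sum(residuals(fit)^2), sum(residuals(lmfit)^2),
               tolerance = 1e-10)
})

test_that("cosinor matches the brute-force grid-search oracle", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(12:24, 1))
    cs <- random_corrected(n, seed + 300)
    fit <- cosinor(cs, period = 90)
    o <- oracle_cosinor_grid(cs$values, cs$times, 90)
    expect_lte(sum(residuals(fit)^2), o$ss + 1e-9)
    expect_lte(abs(coef(fit)[["amplitude"]] - o$amplitude), 2e-3)
    if (o$amplitude > 0.05) {
      expect_lte(ang_diff(coef(fit)[["acrophase"]], o$acrophase), 0.5 + 1e-9)
    }
  }
})

test_that("shifting the time origin rotates the acrophase by 360*shift/period", {
  tm <- 6 + 12 * (0:40)
  y <- 10 + 2 * cos(2 * pi * (tm - 30) / 90) + 0.5 * sin(2 * pi * tm / 50)
  f0 <- cosinor(y, 90, tm)
  for (delta in c(7.5, 12, 33)) {
    f1 <- cosinor(y, 90, tm + delta)
    expect_lte(ang_diff(coef(f1)[["acrophase"]],
                        coef(f0)[["acrophase"]] - 360 * delta / 90), 1e-6)
    expect_equal(coef(f1)[["amplitude"]], coef(f0)[["amplitude"]],
                 tolerance = 1e-9)
    expect_equal(coef(f1)[["mesor"]], coef(f0)[["mesor"]], tolerance = 1e-9)
  }
})

test_that("degenerate trial periods on the grid are rejected", {
  cs <- random_corrected(30, 6)
  # 24-h cosine vanishes on the midpoint 12-h grid
  expect_error(cosinor(cs, 24), class = "circapool_degenerate_design")
  # below twice the sampling interval
  expect_error(cosinor(cs, 12), class = "circapool_validation_error")
})

test_that("spectrum puts a pure 90-h cosine at harmonic 8 of 720 h", {
  tm <- 6 + 12 * (0:59)  # exactly one fundamental span
  y <- 10 + 3 * cos(2 * pi * tm / 90 - pi / 3)
  sp <- ls_spectrum(mk_corrected(y))
  expect_equal(sp$peak$k, 8)
  expect_equal(sp$peak$period, 90)
  expect_equal(sp$peak$percent_rhythm, 1, tolerance = 1e-9)
  others <- sp$table$percent_rhythm[sp$table$k != 8]
  expect_lt(max(others), 1e-9)
  expect_equal(sp$peak_band$k_lo, 8)
  expect_equal(sp$peak_band$k_hi, 8)
  # Nyquist-degenerate harmonic k = 30 dropped, all others fitted
  expect_equal(sp$dropped_harmonics, 30L)
  expect_equal(sp$table$k, setdiff(1:30, 30L))
})

test_that("percent rhythm over the harmonic basis sums to at most one", {
  for (seed in 1:5) {
    cs <- random_corrected(60, seed + 40)
    sp <- ls_spectrum(cs)
    expect_lte(sum(sp$table$percent_rhythm), 1 + 1e-8)
  }
})

test_that("zero-amplitude test holds its type-I error under white noise", {
  # reduced replication of the calibration check run in full by the
  # acceptance suite
  p <- withr::with_seed(99, {
    vapply(1:500, function(i) {
      cosinor(rnorm(63), 90, times = 6 + 12 * (0:62))$p.value
    }, 0)
  })
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.4)  # rate in [0.03, 0.07]
  # p values approximately uniform
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("phase subsets keep their time axis and feed the spectrum", {
  tm <- 6 + 12 * (0:62)
  y <- 10 + 3 * cos(2 * pi * tm / 90 - pi / 2)
  cs <- mk_corrected(y)
  day <- subset_by_phase(cs, "day")
  expect_equal(length(day$values), 32)
  expect_true(all(day$phases == "day"))
  expect_equal(day$times, tm[seq(1, 63, by = 2)])

  # day subset of a pure cosine recovers the same spectral peak
  spd <- ls_spectrum(day)
  expect_equal(spd$peak$k, 8)

  expect_error(acf_series(subset_by_phase(cs, "night")),
               class = "circapool_validation_error")
  expect_error(subset_by_phase(day, "night"),
               class = "circapool_validation_error")
})
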