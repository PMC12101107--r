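# independent oracles (direct formula transcriptions and brute-force
# search) plus small builders shared across test files

# --- builders --------------------------------------------------------------

mk_series <- function(ohdg, volume = 600, creatinine = 1,
                      start_phase = "day", subject = "s") {
  n <- length(ohdg)
  phases <- rep_len(if (start_phase == "day") c("day", "night")
                    else c("night", "day"), n)
  urine_series(subject, (seq_len(n) - 1) * 12, phases,
               rep_len(volume, n), ohdg, rep_len(creatinine, n))
}

mk_corrected <- function(values, start_phase = "day", unit = "ug_per_h") {
  n <- length(values)
  phases <- rep_len(if (start_phase == "day") c("day", "night")
                    else c("night", "day"), n)
  corrected_series("s", 6 + 12 * (seq_len(n) - 1), values, phases, unit)
}

random_corrected <- function(n, seed) {
  withr::with_seed(seed, mk_corrected(exp(rnorm(n, 2, 0.4))))
}

# --- direct-formula oracles ------------------------------------------------

oracle_paired_t <- function(day, night) {
  d <- night - day
  mean(d) / (sd(d) / sqrt(length(d)))
}

oracle_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

oracle_cv <- function(x) {
  100 * sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)
}

oracle_acf <- function(x, k) {
  n <- length(x); m <- mean(x)
  sum((x[seq_len(n - k)] - m) * (x[(k + 1):n] - m)) / sum((x - m)^2)
}

# --- brute-force cosinor oracle -------------------------------------------
# grid search over (M, A, phi): phi scanned at phi_step degrees, A at
# amp_step resolution over [0, max(y)-min(y)]; for fixed (A, phi) the
# optimal mesor is the mean of y - A cos(wt + phi), so the residual SS
# reduces to Syy - 2A Syc + A^2 Scc on centred variables

oracle_cosinor_grid <- function(y, t, period, phi_step = 0.5,
                                amp_step = 1e-3) {
  w <- 2 * pi / period
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  A_grid <- seq(0, max(y) - min(y), by = amp_step)
  phis <- seq(-360 + phi_step, 0, by = phi_step)
  best <- list(ss = Inf)
  for (phi in phis) {
    cvec <- cos(w * t + phi * pi / 180)
    cc <- cvec - mean(cvec)
    Syc <- sum(yc * cc); Scc <- sum(cc^2)
    ss <- Syy - 2 * A_grid * Syc + A_grid^2 * Scc
    i <- which.min(ss)
    if (ss[i] < best$ss) {
      best <- list(ss = ss[i], amplitude = A_grid[i], acrophase = phi,
                   mesor = mean(y) - A_grid[i] * mean(cvec))
    }
  }
  best
}

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  min(d, 360 - d)
}
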