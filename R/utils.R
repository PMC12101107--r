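# internal helpers: classed conditions and small numeric utilities

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_circapool <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "circapool_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

#' @noRd
format_error <- function(msg) stop_circapool(msg, "circapool_format_error")

#' @noRd
validation_error <- function(msg) stop_circapool(msg, "circapool_validation_error")

#' @noRd
config_error <- function(msg) stop_circapool(msg, "circapool_config_error")

# equality on an equidistant grid is checked with a relative tolerance:
# times are stored in hours and typically exact binary fractions
near <- function(x, y, tol = 1e-8) abs(x - y) <= tol * pmax(1, abs(x), abs(y))

#' Sample coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the n-1 denominator in the standard
#' deviation. Errors when the mean is zero.
#'
#' @param x numeric vector, length >= 2.
#' @return percent CV (scalar).
#' @export
cv_percent <- function(x) {
  m <- mean(x)
  if (m == 0) validation_error("CV undefined: mean of the series is zero")
  100 * stats::sd(x) / m
}

# lognormal multiplicative noise with unit mean and given coefficient of
# variation; cv = 0 returns exact ones
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# map an angle in degrees to the acrophase convention (-360, 0];
# angles within 1e-9 deg of the branch cut snap to 0 so a noiseless peak
# at the series start reports exactly 0
canonical_acrophase <- function(deg) {
  out <- deg %% 360          # [0, 360)
  out <- ifelse(out < 1e-9 | out > 360 - 1e-9, 0, out - 360)
  out
}

# smallest absolute difference between two angles in degrees
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
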