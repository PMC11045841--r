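# shared numeric helpers

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`; `c(NA, NA)` when `n == 0`.
#' @examples
#' wilson_ci(134, 200)
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

# shortest signed angular distance a - b on the circle, in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# speed of light in cm/fs: converts an oscillation period in fs to cm^-1
.C_CM_PER_FS <- 2.99792458e-5

#' Convert an oscillation period to a wavenumber
#'
#' @param period_fs Oscillation period in femtoseconds.
#' @return Wavenumber in cm^-1.
#' @examples
#' period_to_wavenumber(33.356)  # ~1000 cm^-1
#' @export
period_to_wavenumber <- function(period_fs) 1 / (period_fs * .C_CM_PER_FS)
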