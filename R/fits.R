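# Excited-state population decay fit, sinusoid period fits, decomposition
# of the average twist into monotonic and oscillatory components, and
# discrete-spectrum frequency estimation.

#' S1 population curve of an ensemble
#'
#' Fraction of trajectories still excited (state S1 or S2) at each time of
#' the frame grid.  Trajectories without a decay count as excited
#' throughout, so the curve equals one minus the empirical CDF of the
#' first-S0 times.
#'
#' @param e An [ensemble()].
#' @return Tibble `time`, `s1_fraction`, `n` (ensemble size).
#' @export
s1_population <- function(e) {
  first_s0 <- vapply(e$trajectories, function(tr) {
    i <- which(tr$states == 0L)
    if (length(i) == 0) Inf else tr$times[i[1]]
  }, numeric(1))
  grid <- sort(unique(unlist(lapply(e$trajectories, function(tr) tr$times))))
  tibble(time = grid,
         s1_fraction = vapply(grid, function(t) mean(first_s0 > t),
                              numeric(1)),
         n = length(e$trajectories))
}

# bounded Levenberg-Marquardt least squares over a named parameter list;
# returns NULL if the optimiser errors, otherwise the parameters and rss
.lm_fit <- function(par, lower, upper, residual_fn) {
  out <- tryCatch(
    minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                       fn = residual_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  list(par = unlist(out$par), rss = sum(out$fvec^2))
}

# lag-plus-two-channel decay law; both factors are clamped to 1 before the
# lag so the curve is flat at 1 until t1
.lifetime_model <- function(t, a1, t1, t2, y0, t3 = NULL) {
  u <- pmax(t - t1, 0)
  g <- exp(-(u / t2)^2)
  e <- exp(-u / (t3 %||% t2))
  a1 * g + y0 + ((1 - a1) - y0) * e
}

#' Fit the S1 population decay
#'
#' Nonlinear least-squares fit of the lag-plus-two-channel decay law
#' \deqn{f(t) = a_1 e^{-((t-t_1)/t_2)^2} + y_0 + ((1-a_1)-y_0)\,
#'   e^{-(t-t_1)/t_2}}
#' in which a Gaussian and an exponential channel share the lag time
#' \eqn{t_1} and decay time \eqn{t_2}; before the lag both factors are
#' clamped to 1.  Initialisation is multi-start: \eqn{t_1} from the decay
#' onset, \eqn{t_2} from the 1/e crossing, several \eqn{a_1} starting
#' values.
#'
#' @param curve Tibble from [s1_population()] (columns `time`,
#'   `s1_fraction`).
#' @param separate_exp_tau If TRUE, the exponential channel gets its own
#'   decay time `t3` (the printed shared-`t2` law is the default).
#' @return Object of class `"isodyn_lifetime_fit"`: fitted parameters, the
#'   fitted curve, the rms residual and the characteristic S1 lifetime
#'   `t1 + t2`.
#' @export
fit_lifetime <- function(curve, separate_exp_tau = FALSE) {
  t <- curve$time
  y <- curve$s1_fraction
  if (length(t) < 10) abort("population curve too short to fit")
  if (max(y) - min(y) < 1e-6) {
    abort("population curve is constant: lifetime undefined",
          class = "isodyn_fit_failure")
  }
  onset <- t[which(y < 0.995 * y[1])[1]] %||% t[2]
  e_cross <- t[which(y < y[1] / exp(1))[1]]
  if (is.na(onset)) onset <- t[2]
  t2_0 <- if (!is.na(e_cross) && e_cross > onset) e_cross - onset
          else diff(range(t)) / 4
  y0_0 <- max(min(y), 1e-4)
  best <- NULL
  for (a1_0 in c(0.2, 0.5, 0.8)) for (t1_0 in unique(c(onset, onset / 2))) {
    start <- list(a1 = a1_0, t1 = max(t1_0, 1e-3), t2 = t2_0, y0 = y0_0)
    lower <- c(a1 = 0, t1 = 0, t2 = 1e-3, y0 = 0)
    upper <- c(a1 = 1, t1 = max(t), t2 = 10 * diff(range(t)), y0 = 1)
    resid_fn <- function(p) {
      y - .lifetime_model(t, p$a1, p$t1, p$t2, p$y0, p$t3)
    }
    if (separate_exp_tau) {
      start$t3 <- t2_0
      lower <- c(lower, t3 = 1e-3)
      upper <- c(upper, t3 = 10 * diff(range(t)))
    }
    fit <- .lm_fit(start, lower, upper, resid_fn)
    if (!is.null(fit) &&
        (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best)) {
    abort("lifetime fit failed to converge from all starts",
          class = "isodyn_fit_failure")
  }
  p <- best$par
  structure(list(
    params = p,
    lifetime = unname(p["t1"] + p["t2"]),
    curve = tibble(time = t, s1_fraction = y,
                   fitted = .lifetime_model(t, p["a1"], p["t1"], p["t2"],
                                            p["y0"],
                                            if (separate_exp_tau) p["t3"])),
    rms = sqrt(best$rss / length(t)),
    separate_exp_tau = separate_exp_tau
  ), class = "isodyn_lifetime_fit")
}

#' @export
print.isodyn_lifetime_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<S1 lifetime fit: a1=%.3f t1=%.1f fs t2=%.1f fs ",
                     "y0=%.3f%s | lifetime t1+t2 = %.1f fs, rms %.2e>\n"),
              p["a1"], p["t1"], p["t2"], p["y0"],
              if (x$separate_exp_tau) sprintf(" t3=%.1f fs", p["t3"]) else "",
              x$lifetime, x$rms))
  invisible(x)
}

#' @export
tidy.isodyn_lifetime_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.isodyn_lifetime_fit <- function(x, ...) {
  tibble(lifetime = x$lifetime, rms = x$rms,
         n = nrow(x$curve))
}

#' Fit a sinusoid to a time series
#'
#' Least-squares fit of `A * sin(2*pi*t/T + phi) + c`.  The period is
#' initialised from the dominant discrete-spectrum frequency (or
#' `period_hint`), and the returned amplitude is normalised to be
#' non-negative with the phase in (-pi, pi].
#'
#' @param data Data frame with a time column and a value column.
#' @param value,time Names of the value and time columns.
#' @param period_hint Optional starting period (fs).
#' @return Object of class `"isodyn_sinusoid_fit"` with fields `amplitude`,
#'   `period`, `phase`, `offset`, `rms`, `flat` (TRUE for a constant input,
#'   in which case the period is NA).
#' @export
fit_sinusoid <- function(data, value = "mean", time = "time",
                         period_hint = NULL) {
  t <- data[[time]]
  y <- data[[value]]
  keep <- !is.na(y) & !is.na(t)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4) abort("too few samples for a sinusoid fit")
  if (sd(y) < 1e-12) {
    return(structure(list(amplitude = 0, period = NA_real_, phase = NA_real_,
                          offset = mean(y), rms = 0, flat = TRUE,
                          curve = tibble(time = t, value = y,
                                         fitted = mean(y))),
                     class = "isodyn_sinusoid_fit"))
  }
  T0 <- period_hint %||% {
    spec <- dominant_frequency(y, dt = stats::median(diff(t)), n_peaks = 1)
    if (nrow(spec) && is.finite(spec$period_fs[1])) spec$period_fs[1]
    else diff(range(t)) / 2
  }
  best <- NULL
  model <- function(p) p$A * sin(2 * pi * t / p$T + p$phi) + p$c0
  for (Tstart in unique(c(T0, T0 * 0.8, T0 * 1.25))) {
    w0 <- 2 * pi / Tstart
    # linear least squares for amplitude/phase/offset at fixed period
    X <- cbind(sin(w0 * t), cos(w0 * t), 1)
    cf <- tryCatch(qr.solve(X, y), error = function(e) c(sd(y), 0, mean(y)))
    start <- list(A = sqrt(cf[1]^2 + cf[2]^2), T = Tstart,
                  phi = atan2(cf[2], cf[1]), c0 = cf[3])
    fit <- .lm_fit(start,
                   lower = c(A = 0, T = 1e-3, phi = -2 * pi, c0 = -Inf),
                   upper = c(A = Inf, T = 100 * diff(range(t)),
                             phi = 2 * pi, c0 = Inf),
                   function(p) y - model(p))
    if (!is.null(fit) &&
        (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best)) abort("sinusoid fit failed to converge",
                           class = "isodyn_fit_failure")
  p <- best$par
  phi <- (p["phi"] + pi) %% (2 * pi) - pi
  structure(list(amplitude = unname(p["A"]), period = unname(p["T"]),
                 phase = unname(phi), offset = unname(p["c0"]),
                 rms = sqrt(best$rss / length(t)), flat = FALSE,
                 curve = tibble(time = t, value = y,
                                fitted = model(as.list(p)))),
            class = "isodyn_sinusoid_fit")
}

#' @export
print.isodyn_sinusoid_fit <- function(x, ...) {
  if (x$flat) {
    cat("<sinusoid fit: flat series, amplitude 0>\n")
  } else {
    cat(sprintf(
      "<sinusoid fit: A=%.3g, T=%.4g fs, phi=%.3f rad, c=%.3g, rms %.2e>\n",
      x$amplitude, x$period, x$phase, x$offset, x$rms))
  }
  invisible(x)
}

#' @export
tidy.isodyn_sinusoid_fit <- function(x, ...) {
  tibble(term = c("amplitude", "period", "phase", "offset"),
         estimate = c(x$amplitude, x$period, x$phase, x$offset))
}

#' @export
glance.isodyn_sinusoid_fit <- function(x, ...) {
  tibble(period = x$period, amplitude = x$amplitude, rms = x$rms,
         flat = x$flat)
}

#' Decompose an average twist curve into monotonic and oscillatory parts
#'
#' Fits a robust linear progression (the monotonic component `alpha_I`)
#' and a sinusoid to the residual (the oscillatory, promoter-coupled
#' component `alpha_II`, typically sharing the wag period).
#'
#' @param data Data frame with time and value columns (e.g. the survivor
#'   average of the twist).
#' @param value,time Column names.
#' @param period_hint Starting period for the oscillatory component (fs),
#'   e.g. the wag period.
#' @param rms_warn Residual rms (deg) above which the result carries a
#'   `poor` flag.
#' @return Object of class `"isodyn_alpha_decomposition"`: `intercept`,
#'   `slope` (deg/fs), `oscillation` (an `isodyn_sinusoid_fit`),
#'   `residual_rms`, `poor`.
#' @export
decompose_alpha <- function(data, value = "mean", time = "time",
                            period_hint = 40, rms_warn = 5) {
  t <- data[[time]]
  y <- data[[value]]
  keep <- !is.na(y)
  t <- t[keep]; y <- y[keep]
  lin <- tryCatch(suppressWarnings(MASS::rlm(y ~ t, maxit = 200)),
                  error = function(e) lm(y ~ t))
  cf <- coef(lin)
  res <- y - (cf[1] + cf[2] * t)
  osc <- fit_sinusoid(tibble(time = t, value = res), value = "value",
                      period_hint = period_hint)
  if (!osc$flat) {
    # joint refinement: the two-stage split leaves a small bias because the
    # linear fit absorbs part of any incomplete oscillation period
    joint <- .lm_fit(
      list(c0 = unname(cf[1]) + osc$offset, c1 = unname(cf[2]),
           A = osc$amplitude, T = osc$period, phi = osc$phase),
      lower = c(c0 = -Inf, c1 = -Inf, A = 0, T = 1e-3, phi = -2 * pi),
      upper = c(c0 = Inf, c1 = Inf, A = Inf,
                T = 100 * diff(range(t)), phi = 2 * pi),
      function(p) y - (p$c0 + p$c1 * t +
                         p$A * sin(2 * pi * t / p$T + p$phi)))
    if (!is.null(joint)) {
      p <- joint$par
      cf <- c(p["c0"], p["c1"])
      phi_n <- (p["phi"] + pi) %% (2 * pi) - pi
      osc$amplitude <- unname(p["A"])
      osc$period <- unname(p["T"])
      osc$phase <- unname(phi_n)
      osc$offset <- 0
    }
  }
  recon <- cf[1] + cf[2] * t +
    if (osc$flat) 0 else
      osc$amplitude * sin(2 * pi * t / osc$period + osc$phase) + osc$offset
  rms <- sqrt(mean((y - recon)^2))
  if (rms > rms_warn) {
    warn(sprintf("alpha decomposition residual rms %.2f deg above %.2f",
                 rms, rms_warn))
  }
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 oscillation = osc, residual_rms = rms,
                 poor = rms > rms_warn,
                 curve = tibble(time = t, value = y, fitted = recon)),
            class = "isodyn_alpha_decomposition")
}

#' Phase of the oscillatory twist component at a queried time
#'
#' @param decomp An `isodyn_alpha_decomposition`.
#' @param t Time(s) in fs.
#' @return Phase `2*pi*t/T + phi` wrapped into `[0, 2*pi)`; used to check
#'   synchronization of the twist oscillation with the wag velocity.
#' @export
sync_phase_at <- function(decomp, t) {
  osc <- decomp$oscillation
  if (osc$flat) abort("no oscillatory component: phase undefined")
  (2 * pi * t / osc$period + osc$phase) %% (2 * pi)
}

#' @export
print.isodyn_alpha_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<alpha decomposition: alpha_I = %.2f %+.3f t deg; ",
                     "alpha_II: A=%.2f deg, T=%.1f fs; residual rms %.3f%s>\n"),
              x$intercept, x$slope, x$oscillation$amplitude,
              x$oscillation$period, x$residual_rms,
              if (x$poor) " (poor)" else ""))
  invisible(x)
}

#' @export
tidy.isodyn_alpha_decomposition <- function(x, ...) {
  tibble(term = c("intercept", "slope", "osc_amplitude", "osc_period",
                  "osc_phase"),
         estimate = c(x$intercept, x$slope, x$oscillation$amplitude,
                      x$oscillation$period, x$oscillation$phase))
}

#' Dominant spectral frequencies of a time series
#'
#' Peaks of the magnitude spectrum of the mean-removed series, refined by
#' parabolic interpolation and converted to wavenumbers.
#'
#' @param y Numeric series on a regular grid.
#' @param dt Sample spacing in fs.
#' @param n_peaks Maximum number of peaks to return (default 2).
#' @return Tibble `period_fs`, `wavenumber_cm1`, `magnitude`, `stable`
#'   (FALSE when the peak barely rises above the median spectral level,
#'   as for white noise).
#' @export
dominant_frequency <- function(y, dt, n_peaks = 2) {
  n <- length(y)
  if (n < 32) abort("need at least 32 samples for a spectrum")
  y <- y - mean(y)
  mag <- Mod(fft(y))[seq_len(floor(n / 2))]
  mag[1] <- 0
  med <- stats::median(mag[-1])
  # local maxima of the magnitude spectrum
  k <- which(diff(sign(diff(mag))) == -2) + 1L
  if (length(k) == 0) k <- which.max(mag)
  k <- k[order(mag[k], decreasing = TRUE)]
  k <- head(k, n_peaks)
  out <- lapply(k, function(kk) {
    # parabolic refinement of the bin position
    delta <- if (kk > 1 && kk < length(mag)) {
      a <- mag[kk - 1]; b <- mag[kk]; cc <- mag[kk + 1]
      den <- a - 2 * b + cc
      if (abs(den) < 1e-300) 0 else 0.5 * (a - cc) / den
    } else 0
    freq <- (kk - 1 + delta) / (n * dt)   # cycles per fs
    tibble(period_fs = 1 / freq,
           wavenumber_cm1 = period_to_wavenumber(1 / freq),
           magnitude = mag[kk],
           stable = mag[kk] > 5 * med)
  })
  dplyr::bind_rows(out)
}
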