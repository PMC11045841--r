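test_that("the S1 population curve is one minus the hop-time ECDF", {
  t <- 0:30
  tr1 <- angle_trajectory("a", -t, -t, times = t,
                          states = ifelse(t < 10, 1L, 0L))
  tr2 <- angle_trajectory("b", -t, -t, times = t,
                          states = ifelse(t < 20, 1L, 0L))
  e <- ensemble(list(tr1, tr2), dihedral_map = fragment_dihedral_map())
  pop <- s1_population(e)
  expect_equal(pop$s1_fraction[pop$time < 10], rep(1, 10))
  expect_equal(pop$s1_fraction[pop$time >= 10 & pop$time < 20], rep(0.5, 10))
  expect_equal(pop$s1_fraction[pop$time >= 20], rep(0, 11))

  # no decays: constant 1
  e2 <- ensemble(list(angle_trajectory("c", -t, -t, times = t)),
                 dihedral_map = fragment_dihedral_map())
  expect_equal(s1_population(e2)$s1_fraction, rep(1, 31))
})

test_that("a generated ensemble's curve equals 1 - ECDF of first-S0 times", {
  g <- generate_ensemble(preset_config("rh_like"), seed = 17)
  pop <- s1_population(g$ensemble)
  first_s0 <- vapply(g$ensemble$trajectories, function(tr) {
    i <- which(tr$states == 0L)
    if (length(i) == 0) Inf else tr$times[i[1]]
  }, numeric(1))
  oracle <- vapply(pop$time, function(t) mean(first_s0 > t), numeric(1))
  expect_equal(pop$s1_fraction, oracle)
})

test_that("the decay-law fit recovers noiseless parameters within 1%", {
  t <- seq(0, 400, by = 1)
  truth <- c(a1 = 0.3, t1 = 50, t2 = 80, y0 = 0.02)
  y <- isodyn:::.lifetime_model(t, truth["a1"], truth["t1"], truth["t2"],
                                truth["y0"])
  fit <- fit_lifetime(tibble::tibble(time = t, s1_fraction = y))
  expect_equal(unname(fit$params[names(truth)]), unname(truth),
               tolerance = 0.01)
  expect_lt(fit$rms, 1e-4)
  expect_equal(fit$lifetime, 130, tolerance = 0.01)
})

test_that("degenerate population curves are rejected or flagged", {
  t <- seq(0, 200, by = 1)
  expect_error(fit_lifetime(tibble::tibble(time = t, s1_fraction = rep(1, 201))),
               class = "isodyn_fit_failure")
  # step curve: the lag lands at the step and the decay time is short
  y <- ifelse(t < 100, 1, 0)
  fit <- fit_lifetime(tibble::tibble(time = t, s1_fraction = y))
  expect_equal(unname(fit$params["t1"]), 100, tolerance = 0.05)
  expect_lt(unname(fit$params["t2"]), 10)
})

test_that("tidy and glance methods expose the fit", {
  t <- seq(0, 300, by = 2)
  y <- isodyn:::.lifetime_model(t, 0.4, 40, 60, 0.05)
  fit <- fit_lifetime(tibble::tibble(time = t, s1_fraction = y))
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("a1", "t1", "t2", "y0"))
  gl <- generics::glance(fit)
  expect_named(gl, c("lifetime", "rms", "n"))
})

test_that("sinusoid fitting is exact on clean data and robust to noise", {
  t <- seq(0, 200, by = 1)
  y <- 3 * sin(2 * pi * t / 40 + 0.5) + 1
  fit <- fit_sinusoid(tibble::tibble(time = t, value = y), value = "value")
  expect_equal(fit$period, 40, tolerance = 0.1 / 40)
  expect_equal(fit$amplitude, 3, tolerance = 1e-3)
  expect_equal(fit$offset, 1, tolerance = 1e-3)

  # 5% white noise on a slow 250 fs oscillation: period within 2% per seed
  t2 <- seq(0, 600, by = 1)
  for (s in 1:5) {
    set.seed(s)
    y2 <- 2 * sin(2 * pi * t2 / 250 + 1) + rnorm(length(t2), 0, 0.1)
    fit2 <- fit_sinusoid(tibble::tibble(time = t2, value = y2),
                         value = "value")
    expect_equal(fit2$period, 250, tolerance = 0.02)
  }
})

test_that("a constant series yields zero amplitude and no period", {
  fit <- fit_sinusoid(tibble::tibble(time = 0:50, value = rep(2, 51)),
                      value = "value")
  expect_true(fit$flat)
  expect_equal(fit$amplitude, 0)
  expect_true(is.na(fit$period))
})

test_that("twist decomposition separates drift and oscillation", {
  t <- seq(0, 200, by = 1)
  y <- -0.5 * t + 3 * sin(2 * pi * t / 40)
  d <- decompose_alpha(tibble::tibble(time = t, value = y), value = "value",
                       period_hint = 40)
  expect_equal(d$slope, -0.5, tolerance = 0.02)
  expect_equal(d$oscillation$period, 40, tolerance = 0.02)
  expect_equal(d$oscillation$amplitude, 3, tolerance = 0.02)
  expect_lt(d$residual_rms, 0.1)

  lin <- decompose_alpha(tibble::tibble(time = t, value = -1.2 * t + 4),
                         value = "value", period_hint = 40)
  expect_lt(lin$oscillation$amplitude, 1e-3)
  pure <- decompose_alpha(tibble::tibble(time = t,
                                         value = 5 * sin(2 * pi * t / 60)),
                          value = "value", period_hint = 60)
  expect_lt(abs(pure$slope), 0.01)
  expect_equal(pure$oscillation$period, 60, tolerance = 0.02)
})

test_that("the oscillation phase is queryable for synchronization analysis", {
  t <- seq(0, 200, by = 1)
  y <- -0.5 * t + 3 * sin(2 * pi * t / 40 + 0.8)
  d <- decompose_alpha(tibble::tibble(time = t, value = y), value = "value",
                       period_hint = 40)
  ph <- sync_phase_at(d, c(0, 10))
  expect_equal((ph[2] - ph[1]) %% (2 * pi), 2 * pi * 10 / 40,
               tolerance = 0.05)
})

test_that("spectral peaks convert periods to wavenumbers correctly", {
  # unit identity: 33.356 fs period ~ 1000 cm^-1
  expect_equal(period_to_wavenumber(1 / 2.99792458e-5 / 1000), 1000)
  dt <- 0.5
  t <- seq(0, 2047 * dt, by = dt)
  y <- sin(2 * pi * t / 33.356)
  pk <- dominant_frequency(y, dt, n_peaks = 1)
  expect_equal(pk$wavenumber_cm1, 1000, tolerance = 0.01)

  y2 <- sin(2 * pi * t / 40) + 0.8 * sin(2 * pi * t / 20 + 1)
  pk2 <- dominant_frequency(y2, dt, n_peaks = 2)
  wn <- sort(pk2$wavenumber_cm1)
  expect_equal(wn[1], period_to_wavenumber(40), tolerance = 0.01)
  expect_equal(wn[2], period_to_wavenumber(20), tolerance = 0.01)
  expect_true(all(pk2$stable))
})

test_that("white noise has no stable spectral peak", {
  set.seed(3)
  flagged <- vapply(1:5, function(i) {
    pk <- dominant_frequency(rnorm(512), dt = 1, n_peaks = 1)
    pk$stable
  }, logical(1))
  expect_lt(mean(flagged), 0.5)
})
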