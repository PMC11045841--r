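test_that("condition table fractions match hand enumeration", {
  rec <- make_records(dtau = c(-2, -0.5, 0.5, -1.5),
                      reactive = c(TRUE, FALSE, FALSE, TRUE))
  ct <- condition_table(rec)
  expect_equal(ct$phi_iso, 0.5)
  expect_equal(ct$frac_dtau_neg, 0.75)
  expect_equal(ct$p_neg_given_reactive, 1)
  expect_equal(ct$p_reactive_given_neg, 2 / 3)
  expect_equal(ct$frac_in_band_of_neg, 1 / 3)
  expect_equal(ct$p_reactive_given_band, 0)
})

test_that("all-reactive all-negative population gives unit fractions", {
  rec <- make_records(dtau = c(-2, -3, -1.4), reactive = rep(TRUE, 3))
  ct <- condition_table(rec)
  expect_equal(ct$phi_iso, 1)
  expect_equal(ct$frac_dtau_neg, 1)
  expect_equal(ct$p_neg_given_reactive, 1)
  expect_equal(ct$p_reactive_given_neg, 1)
})

test_that("a zero decay velocity counts as non-negative", {
  rec <- make_records(dtau = c(0, -1), reactive = c(TRUE, TRUE))
  ct <- condition_table(rec)
  expect_equal(ct$frac_dtau_neg, 0.5)
  expect_equal(ct$p_neg_given_reactive, 0.5)
})

test_that("law of total probability holds exactly on random populations", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    rec <- make_records(dtau = round(rnorm(n, -0.5, 1.2), 3),
                        reactive = runif(n) < 0.6)
    ct <- condition_table(rec)
    lhs <- ct$phi_iso
    rhs <- ct$p_reactive_given_neg * ct$frac_dtau_neg +
      ct$p_reactive_given_pos * (1 - ct$frac_dtau_neg)
    if (is.na(rhs)) rhs <- ct$p_reactive_given_neg * ct$frac_dtau_neg
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("phi of a merged ensemble is the count-weighted mean", {
  set.seed(4)
  ra <- make_records(dtau = rnorm(30, -1), reactive = runif(30) < 0.7)
  rb <- make_records(dtau = rnorm(50, -0.2), reactive = runif(50) < 0.4)
  merged <- dplyr::bind_rows(ra, rb)
  attr(merged, "n_total") <- 80
  ca <- condition_table(ra); cb <- condition_table(rb)
  cm <- condition_table(merged)
  expect_equal(cm$phi_iso, (30 * ca$phi_iso + 50 * cb$phi_iso) / 80,
               tolerance = 1e-12)
})

test_that("the Wilson interval matches the score-test oracle", {
  for (kn in list(c(134, 200), c(3, 10), c(0, 25), c(25, 25))) {
    ours <- wilson_ci(kn[1], kn[2])
    oracle <- stats::prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(ours, as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("the interval covers the generator's construction efficiency", {
  g <- generate_ensemble(preset_config("rh_like"), seed = 21)
  ht <- hop_table(g$ensemble)
  ct <- condition_table(ht)
  phi_true <- mean(g$ledger$reactive, na.rm = TRUE)
  expect_gte(phi_true, ct$phi_iso_lo)
  expect_lte(phi_true, ct$phi_iso_hi)
})

test_that("velocity histogram bins and totals are consistent", {
  rec <- make_records(dtau = c(-0.5), reactive = TRUE)
  h <- velocity_histogram(rec)
  coarse <- h[h$scale == "coarse", ]
  expect_equal(coarse$n_reactive[coarse$lo == -1 & coarse$hi == 0], 1L)
  expect_equal(sum(coarse$n_reactive) + sum(coarse$n_unreactive), 1L)

  # ten uniform draws in [-10, 0): all counts on the negative side
  set.seed(8)
  v <- runif(10, -10, -1e-6)
  rec10 <- make_records(dtau = v, reactive = rep(c(TRUE, FALSE), 5))
  h10 <- velocity_histogram(rec10)
  c10 <- h10[h10$scale == "coarse", ]
  expect_equal(sum(c10$n_reactive + c10$n_unreactive), 10L)
  expect_equal(sum(c10$n_reactive[c10$hi <= 0] +
                     c10$n_unreactive[c10$hi <= 0]), 10L)
  # direct binning oracle
  oracle <- table(cut(v, breaks = seq(-10, 10, 1), right = FALSE))
  expect_equal(unname(c10$n_reactive + c10$n_unreactive),
               unname(as.integer(oracle)))
})

test_that("mirrored velocity sets give mirrored histograms", {
  v <- c(-3.2, -1.6, -0.4, -2.8)
  ha <- velocity_histogram(make_records(dtau = v, reactive = rep(TRUE, 4)))
  hb <- velocity_histogram(make_records(dtau = -v + 1e-9,
                                        reactive = rep(TRUE, 4)))
  ca <- ha[ha$scale == "coarse", ]
  cb <- hb[hb$scale == "coarse", ]
  expect_equal(ca$n_reactive, rev(cb$n_reactive))
})

test_that("decay window reports IDT and DTL with a robust variant", {
  rec <- make_records(dtau = rep(-1, 3), reactive = rep(TRUE, 3),
                      hop_time = c(30, 100, 180))
  dw <- decay_window(rec)
  expect_equal(dw$idt, 30)
  expect_equal(dw$dtl, 150)
  same <- make_records(dtau = rep(-1, 3), reactive = rep(TRUE, 3),
                       hop_time = rep(55, 3))
  expect_equal(decay_window(same)$dtl, 0)
  one <- make_records(dtau = -1, reactive = TRUE, hop_time = 10)
  expect_error(decay_window(one), "fewer than 2")
})

test_that("survivor averages track the undecayed population only", {
  t <- 0:20
  tr1 <- angle_trajectory("a", -1 * t, -1 * t, times = t)
  tr2 <- angle_trajectory("b", -2 * t, -2 * t, times = t,
                          states = ifelse(t <= 10, 1L, 0L))
  e <- ensemble(list(tr1, tr2), dihedral_map = fragment_dihedral_map())
  avg <- ensemble_average(ensemble_series(e), "alpha")
  both <- avg$time <= 10
  expect_equal(avg$mean[both], -1.5 * avg$time[both], tolerance = 1e-6)
  expect_equal(avg$n_surviving[both], rep(2L, sum(both)))
  after <- avg$time > 10
  expect_equal(avg$mean[after], -1 * avg$time[after], tolerance = 1e-6)
  expect_equal(avg$n_surviving[after], rep(1L, sum(after)))

  # single trajectory: the average is the trajectory
  e1 <- ensemble(list(tr1), dihedral_map = fragment_dihedral_map())
  avg1 <- ensemble_average(ensemble_series(e1), "alpha")
  expect_equal(avg1$mean, -1 * avg1$time, tolerance = 1e-6)
})

test_that("the generator's wag amplitude survives ensemble averaging", {
  # common wag phase: the survivor-averaged -0.5 d_delta_op/dt amplitude
  # must recover the generating amplitude within 5%
  cfg <- preset_config("rh_like", n_traj = 40, wag_phase_sd = 0,
                       hop_jitter_sd = 0, drift_sd = 0.2)
  g <- generate_ensemble(cfg, seed = 13)
  ser <- ensemble_series(g$ensemble)
  avg <- ensemble_average(ser, "d_delta_op")
  avg <- avg[avg$n_surviving >= 30, ]
  avg$mean <- -0.5 * avg$mean
  fit <- fit_sinusoid(avg, period_hint = cfg$wag_period)
  amp_true <- 0.5 * cfg$wag_amp * 2 * pi / cfg$wag_period
  expect_equal(fit$amplitude, amp_true, tolerance = 0.05)
  expect_equal(fit$period, cfg$wag_period, tolerance = 0.02)
})
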