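test_that("find_decay locates the first S1->S0 transition", {
  tr <- angle_trajectory("a", seq(0, -40, by = -10), seq(0, -40, by = -10),
                         states = c(1, 1, 1, 0, 0))
  expect_equal(find_decay(tr)$frame, 4L)   # first S0 frame
  tr2 <- angle_trajectory("b", c(0, -10, -20), c(0, -10, -20),
                          states = c(1, 1, 1))
  expect_error(find_decay(tr2), class = "isodyn_no_decay")
  # S2->S1 relaxation is ignored; only the S1->S0 hop counts
  tr3 <- angle_trajectory("c", c(0, -10, -20), c(0, -10, -20),
                          states = c(2, 1, 0))
  expect_equal(find_decay(tr3)$frame, 3L)
  # re-crossings: the first hop defines the decay
  tr4 <- angle_trajectory("d", seq(0, -50, by = -10), seq(0, -50, by = -10),
                          states = c(1, 1, 0, 1, 0, 0))
  expect_equal(find_decay(tr4)$frame, 3L)
})

test_that("find_decay falls back to the hop sidecar when states are flat", {
  tr <- angle_trajectory("a", c(0, -10, -20, -30), c(0, -10, -20, -30),
                         states = c(1, 1, 1, 1),
                         hops = tibble::tibble(frame = 3L, from = 1L,
                                               to = 0L))
  expect_equal(find_decay(tr)$frame, 3L)
})

test_that("classification windows separate product, reactant and undecided", {
  expect_equal(classify_outcome(-178), "reactive")
  expect_equal(classify_outcome(6), "unreactive")
  expect_equal(classify_outcome(-95), "undecided")
  expect_equal(classify_outcome(182), "reactive")    # wraps onto -178
  # invariant under whole-series 360-degree shifts
  for (end in c(-178, 6, -95, -200, 44)) {
    expect_equal(classify_outcome(end + 360), classify_outcome(end))
    expect_equal(classify_outcome(end - 360), classify_outcome(end))
  }
})

test_that("decay observables are evaluated on the last S1 frame", {
  t <- 0:100
  states <- ifelse(t <= 90, 1L, 0L)     # hop after t = 90
  tr <- angle_trajectory("lin", -1 * t, -1 * t, times = t, states = states)
  rec <- decay_observables(tr, derive_series(tr, fragment_dihedral_map()))
  expect_equal(rec$hop_time, 90)
  expect_equal(rec$alpha_decay, -90, tolerance = 1e-6)
  expect_equal(rec$dalpha_decay, -1, tolerance = 1e-6)
  # pure twist: no wag, so tau velocity equals alpha velocity
  expect_equal(rec$dtau_decay, rec$dalpha_decay, tolerance = 1e-9)
  expect_equal(rec$delta_op_decay, 0, tolerance = 1e-6)
  expect_false(rec$short_tail)
})

test_that("early hops and short tails are flagged", {
  tr <- angle_trajectory("early", c(0, -90, -120), c(0, -90, -120),
                         states = c(1, 0, 0))
  rec <- decay_observables(tr, derive_series(tr, fragment_dihedral_map()))
  expect_false(rec$velocity_defined)
  expect_true(rec$short_tail)
})

test_that("decay records match the generator ledger", {
  g <- generate_ensemble(preset_config("rh_like", n_traj = 30), seed = 11)
  ht <- hop_table(g$ensemble)
  led <- g$ledger[!is.na(g$ledger$hop_frame), ]
  merged <- merge(ht, led, by = "traj_id")
  expect_equal(nrow(merged), nrow(ht))
  expect_equal(merged$hop_frame.x, merged$hop_frame.y)
  expect_equal(merged$hop_time.x, merged$hop_time.y)
  expect_lt(max(abs(merged$dtau_decay.x - merged$dtau_decay.y)), 1e-6)
})

test_that("classifier labels agree with generator ground truth", {
  # off-boundary agreement must be exact; boundary cases near the
  # threshold are still consistent because the post-hop relaxation target
  # is set by the drawn label
  for (s in 1:3) {
    g <- generate_ensemble(preset_config("rh_like", n_traj = 50), seed = s)
    ht <- hop_table(g$ensemble)
    cl <- ht[ht$outcome != "undecided", ]
    led <- g$ledger[match(cl$traj_id, g$ledger$traj_id), ]
    expect_equal(cl$outcome == "reactive", led$reactive)
  }
})

test_that("undecayed trajectories are excluded or counted per the switch", {
  cfg <- preset_config("rh_like", n_traj = 6, horizon = 20)  # too short
  g <- generate_ensemble(cfg, seed = 2)
  ht_ex <- hop_table(g$ensemble)
  ht_un <- hop_table(g$ensemble, undecayed = "unreactive")
  expect_equal(attr(ht_ex, "n_no_decay") + nrow(ht_ex), 6L)
  expect_equal(nrow(ht_un), 6L)
  expect_true(all(ht_un$outcome[is.na(ht_un$hop_time)] == "unreactive"))
})
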