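# Kinematic ensemble generator.
#
# Each trajectory prescribes the double-bond twist alpha(t) as a monotonic
# drift towards -90 deg plus an oscillatory component, and the wag
# delta_op(t) as the sum of a fast (HOOP-like) and a slow (ring-inversion,
# promoter-like) sinusoid; beta = alpha - delta_op.  The S1->S0 hop occurs
# at a downward crossing of the twist through the crossing angle, and the
# outcome is set from the overlap-dihedral velocity at decay following a
# Landau-Zener-motivated rule: fast pi-bond breaking (d_tau strongly
# negative) always yields product, slow crossings are randomized, and
# positive d_tau (bond re-making) yields product only rarely.

#' Generator configuration
#'
#' @param n_traj Number of trajectories.
#' @param dt Frame spacing in fs.
#' @param horizon Propagation length in fs.
#' @param drift_mean,drift_sd Mean and s.d. of the per-trajectory twist
#'   drift d(alpha_I)/dt in deg/fs (negative: counterclockwise).
#' @param drift_cap Upper (least negative) bound applied to sampled drifts,
#'   deg/fs; keeps every trajectory moving towards the crossing.
#' @param alpha_osc_amp Amplitude (deg) of the twist oscillation alpha_II;
#'   shares period and phase with the fast wag.
#' @param wag_amp,wag_period,wag_phase_sd Fast wag oscillation of
#'   `delta_op`: amplitude (deg), period (fs) and across-trajectory phase
#'   jitter (radians; small values give a vibrationally coherent ensemble).
#' @param wag_phase_offset Phase of the wag relative to the twist
#'   oscillation (radians).  The default `pi` anti-phases the two, so that
#'   while the twist oscillation descends towards the crossing the wag
#'   velocity also drives the overlap dihedral negative -- the promoter
#'   synchronization that enlarges the reactive decay-velocity amplitude.
#' @param promoter_amp,promoter_period,promoter_phase_sd Slow promoter
#'   oscillation injected into `delta_op` (ring-inversion-like); a `rho`
#'   series proportional to it is also prescribed.
#' @param hop_angle Crossing angle in degrees (default -90).
#' @param hop_prob Per-frame hop probability once the twist has reached
#'   the crossing region; the trajectory lingers near the intersection
#'   seam until the hop fires.
#' @param hop_jitter_sd S.d. (deg) of the per-trajectory crossing angle.
#' @param theta Velocity threshold (deg/fs) above which the outcome is
#'   deterministic (reactive for d_tau < -theta).
#' @param q_neg Reactive probability for decays with
#'   `-theta < d_tau < 0` (sub-threshold bond breaking).
#' @param q_pos Reactive probability for decays with `d_tau >= 0`
#'   (bond re-making; rarely reactive).
#' @param relax_tc Post-hop exponential relaxation time constant (fs).
#' @return A list of class `"isodyn_generator_config"`.
#' @export
generator_config <- function(n_traj = 200, dt = 1, horizon = 200,
                             drift_mean = -1.5, drift_sd = 0.5,
                             drift_cap = -0.5,
                             alpha_osc_amp = 8,
                             wag_amp = 45, wag_period = 40,
                             wag_phase_sd = 0.5, wag_phase_offset = pi,
                             promoter_amp = 0, promoter_period = 250,
                             promoter_phase_sd = 0.5,
                             hop_angle = -90, hop_prob = 0.7,
                             hop_jitter_sd = 5,
                             theta = 1.0, q_neg = 0.5, q_pos = 0.12,
                             relax_tc = 25) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_traj >= 1, cfg$dt > 0, cfg$horizon > 0,
            cfg$wag_period > 0, cfg$promoter_period > 0,
            cfg$hop_prob >= 0, cfg$hop_prob <= 1,
            cfg$q_neg >= 0, cfg$q_neg <= 1, cfg$q_pos >= 0, cfg$q_pos <= 1,
            cfg$theta >= 0, cfg$relax_tc > 0)
  structure(cfg, class = "isodyn_generator_config")
}

#' Preset generator configurations
#'
#' `rh_like` emulates the rhodopsin-bound chromophore: fast, coherent decay
#' (first hops near 30 fs, decay window ~150 fs) driven by a large-amplitude
#' 40 fs wag promoter.  `naip_like` emulates the solvated synthetic rotor:
#' slow decay (first hops beyond 100 fs, window >250 fs), a weak fast wag
#' and a quenched slow promoter.  `naip_gas_like` emulates the isolated
#' rotor, where a coherent 250 fs ring-inversion promoter is active.
#'
#' @param preset One of `"rh_like"`, `"naip_like"`, `"naip_gas_like"`.
#' @param ... Overrides passed to [generator_config()].
#' @return A generator configuration.
#' @export
preset_config <- function(preset = c("rh_like", "naip_like", "naip_gas_like"),
                          ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    rh_like = list(n_traj = 200, horizon = 220,
                   drift_mean = -1.5, drift_sd = 0.5, drift_cap = -0.55,
                   alpha_osc_amp = 8,
                   wag_amp = 30, wag_period = 40, wag_phase_sd = 0.9,
                   wag_phase_offset = 1.1,
                   promoter_amp = 0,
                   hop_prob = 0.7, relax_tc = 25),
    naip_like = list(n_traj = 200, horizon = 620,
                     drift_mean = -0.32, drift_sd = 0.10, drift_cap = -0.16,
                     alpha_osc_amp = 0,
                     wag_amp = 6, wag_period = 40, wag_phase_sd = 1.5,
                     wag_phase_offset = 0,
                     promoter_amp = 10, promoter_period = 250,
                     promoter_phase_sd = 1.5,
                     hop_prob = 0.7, relax_tc = 40),
    naip_gas_like = list(n_traj = 200, horizon = 620,
                         drift_mean = -0.45, drift_sd = 0.12,
                         drift_cap = -0.2,
                         alpha_osc_amp = 0,
                         wag_amp = 6, wag_period = 40, wag_phase_sd = 1.5,
                         wag_phase_offset = 0,
                         promoter_amp = 40, promoter_period = 250,
                         promoter_phase_sd = 0.3,
                         hop_prob = 0.7, relax_tc = 40))
  over <- list(...)
  do.call(generator_config, utils::modifyList(base, over))
}

#' Embed twist and wag angles as a 6-atom Cartesian frame
#'
#' Builds the minimal ethylenic fragment C1, C2, C3, C4, R1, R4 (skeletal
#' and ethylenic substituents of the isomerizing double bond) from internal
#' coordinates (bond lengths 1.45 / 1.40 / 1.45 Angstrom, 1.08 to R,
#' 120 degree bond angles) so that the C1-C2-C3-C4 dihedral reads back
#' `alpha` and R1-C2-C3-R4 reads back `beta`.
#'
#' @param alpha,beta Dihedral angles in degrees (recycled to a common
#'   length).
#' @return Array of dimension `c(n, 6, 3)` of coordinates in Angstrom.
#' @export
embed_xyz <- function(alpha, beta) {
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, n)
  beta <- rep_len(beta, n)
  s <- sin(pi / 3)   # sin 60: xy-projection of a 120-degree bond
  coords <- array(NA_real_, dim = c(n, 6, 3))
  on2 <- function(psi, L) {        # substituent bonded to C2 at (0,0,0)
    cbind(L * s * cos(psi), L * s * sin(psi), -L / 2)
  }
  on3 <- function(psi, L) {        # substituent bonded to C3 at (0,0,1.40)
    cbind(L * s * cos(psi), L * s * sin(psi), 1.40 + L / 2)
  }
  # dihedral(X1-C2-C3-X4) = -(psi4 - psi1) under the IUPAC sign convention
  a <- deg2rad(alpha)
  b <- deg2rad(beta)
  coords[, 1, ] <- on2(rep(0, n), 1.45)        # C1
  coords[, 2, ] <- matrix(0, n, 3)             # C2
  coords[, 3, ] <- matrix(rep(c(0, 0, 1.40), each = n), n, 3)  # C3
  coords[, 4, ] <- on3(-a, 1.45)               # C4
  coords[, 5, ] <- on2(rep(pi, n), 1.08)       # R1
  coords[, 6, ] <- on3(pi - b, 1.08)           # R4
  coords
}

# prescribe one trajectory's angle series and hop from sampled parameters
.generate_one <- function(cfg, id, drift, phi_wag, phi_prom, hop_level,
                          unif_cross, unif_outcome) {
  t <- seq(0, cfg$horizon, by = cfg$dt)
  w_f <- 2 * pi / cfg$wag_period
  w_s <- 2 * pi / cfg$promoter_period
  fast <- sin(w_f * t + phi_wag)
  slow <- sin(w_s * t + phi_prom)
  alpha <- drift * t + cfg$alpha_osc_amp * fast
  delta <- cfg$wag_amp * sin(w_f * t + phi_wag + cfg$wag_phase_offset) +
    cfg$promoter_amp * slow
  rho <- 1.5 * cfg$promoter_amp * slow         # ring dihedral proportional
                                               # to the slow promoter
  # once the twist reaches the (jittered) crossing level the trajectory
  # lingers in the intersection region and hops with a per-frame
  # probability; the frame where the hop fires is the last S1 frame
  n <- length(t)
  k0 <- which(alpha <= hop_level)[1]
  hop_frame <- NA_integer_
  if (!is.na(k0) && max(k0, 2L) <= n - 1L) {
    for (j in seq.int(max(k0, 2L), n - 1L)) {
      u_idx <- j - max(k0, 2L) + 1L
      u <- if (u_idx <= length(unif_cross)) unif_cross[u_idx] else 0
      if (u < cfg$hop_prob) {
        hop_frame <- j + 1L        # first S0 frame
        break
      }
    }
  }
  if (is.na(hop_frame) || hop_frame < 3L) {
    return(list(alpha = alpha, beta = alpha - delta, rho = rho, times = t,
                states = rep(1L, n), hop_frame = NA_integer_,
                dtau_decay = NA_real_, reactive = NA, id = id,
                drift = drift))
  }
  k <- hop_frame - 1L              # last S1 frame: the decay point
  tau <- alpha - 0.5 * delta
  dtau <- (tau[k] - tau[k - 1L]) / (t[k] - t[k - 1L])  # backward difference
  reactive <-
    if (dtau < -cfg$theta) TRUE
    else if (dtau < 0) unif_outcome < cfg$q_neg
    else unif_outcome < cfg$q_pos
  target <- if (reactive) -180 else 0
  post <- hop_frame:n
  decay <- exp(-(t[post] - t[k]) / cfg$relax_tc)
  alpha[post] <- target + (alpha[k] - target) * decay
  delta[post] <- delta[k] * decay
  states <- rep(1L, n)
  states[post] <- 0L
  list(alpha = alpha, beta = alpha - delta, rho = rho, times = t,
       states = states, hop_frame = hop_frame, dtau_decay = dtau,
       reactive = reactive, id = id, drift = drift)
}

#' Generate a labeled synthetic trajectory ensemble
#'
#' Draws per-trajectory drifts and oscillation phases from the
#' configuration, prescribes twist/wag angle series, embeds them as 6-atom
#' XYZ frames via [embed_xyz()], and records ground truth (prescribed
#' series, hop frame, decay velocity and outcome label) in a ledger so the
#' analysis pipeline can be validated against construction.
#'
#' @param cfg A [generator_config()] or [preset_config()].
#' @param seed Integer RNG seed; the ensemble is fully reproducible from it.
#' @return A list with elements `ensemble` (an [ensemble()] carrying the
#'   [fragment_dihedral_map()]) and `ledger` (a tibble with one row per
#'   trajectory: sampled parameters, `hop_frame`, `hop_time`,
#'   `dtau_decay` in deg/fs and the ground-truth `reactive` label, plus a
#'   list column `series` with the prescribed angle series).
#' @export
generate_ensemble <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "isodyn_generator_config"))
  set.seed(seed)
  n <- cfg$n_traj
  drift <- pmin(rnorm(n, cfg$drift_mean, cfg$drift_sd), cfg$drift_cap)
  phi_wag <- rnorm(n, 0, cfg$wag_phase_sd)
  phi_prom <- rnorm(n, 0, cfg$promoter_phase_sd)
  hop_level <- cfg$hop_angle + rnorm(n, 0, cfg$hop_jitter_sd)
  unif_cross <- matrix(runif(n * 25), n, 25)
  unif_outcome <- runif(n)
  ids <- sprintf("traj%03d", seq_len(n))

  gens <- lapply(seq_len(n), function(i) {
    .generate_one(cfg, ids[i], drift[i], phi_wag[i], phi_prom[i],
                  hop_level[i], unif_cross[i, ], unif_outcome[i])
  })
  trajs <- lapply(gens, function(g) {
    coords <- embed_xyz(g$alpha, g$beta)
    hops <- if (!is.na(g$hop_frame)) {
      tibble(frame = g$hop_frame, from = 1L, to = 0L)
    }
    trajectory(g$id, coords, g$times, g$states, hops = hops,
               meta = list(atom_labels = c("C", "C", "C", "C", "H", "H")))
  })
  ledger <- tibble(
    traj_id = ids,
    drift = drift, phi_wag = phi_wag, phi_prom = phi_prom,
    hop_level = hop_level,
    hop_frame = vapply(gens, function(g) g$hop_frame, integer(1)),
    hop_time = vapply(gens, function(g) {
      if (is.na(g$hop_frame)) NA_real_ else g$times[g$hop_frame - 1L]
    }, numeric(1)),
    dtau_decay = vapply(gens, function(g) g$dtau_decay, numeric(1)),
    reactive = vapply(gens, function(g) g$reactive, logical(1)),
    series = lapply(gens, function(g) {
      tibble(time = g$times, alpha = g$alpha, beta = g$beta, rho = g$rho)
    })
  )
  list(ensemble = ensemble(trajs, dihedral_map = fragment_dihedral_map(),
                           dt = cfg$dt),
       ledger = ledger)
}
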