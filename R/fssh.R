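# Minimal two-state, two-mode fewest-switches surface-hopping simulator.
#
# The model Hamiltonian couples a periodic twist coordinate theta (radians,
# mapped to the twist angle alpha on output) and a harmonic wag coordinate
# q (mapped to delta_op) through diabatic potentials
#   V11 = 0.5*w1*(1 - cos 2*theta) + 0.5*mq*wq^2*q^2
#   V22 = de  + 0.5*w2*(1 + cos 2*theta) + 0.5*mq*wq^2*q^2
#   V12 = lam*q + v12_const
# Model units: hbar = 1, time in fs, energy in hbar/fs.  With de < w1 the
# upper adiabatic surface is barrierless from the (pre-twisted)
# Franck-Condon region down to a conical intersection near theta = -90 deg
# at q = 0, echoing the twist-driven topography of the photoisomerization
# problem; no chemical accuracy is claimed.
#
# Nuclear motion: velocity Verlet on the current adiabatic surface.
# Electronic amplitudes: norm-conserving split (phase / coupling rotation /
# phase) on a finer substep, with the nonadiabatic coupling evaluated from
# finite-difference eigenvector overlaps.  Hops follow the fewest-switches
# probability; on a hop the velocity is rescaled along the nonadiabatic
# coupling direction (frustrated hops reverse that component).  The
# inactive amplitude is damped by the energy-based decoherence time
# (1/|dE|)*(1 + C/Ekin) after every nuclear step.

#' Two-state two-mode model Hamiltonian
#'
#' @param w1 Ground-state torsional barrier (model energy units).
#' @param w2 Excited-state torsional amplitude; the upper diabat descends
#'   from the Franck-Condon region towards the crossing.
#' @param de Vertical energy offset; `de < w1` places the diabatic crossing
#'   before -90 deg with a finite slope difference.
#' @param mq,wq Mass and angular frequency of the harmonic wag mode
#'   (`wq = 2*pi/40` gives a 40 fs wag period).
#' @param itheta Moment of inertia of the twist.
#' @param lam Linear vibronic coupling strength (`V12 = lam * q`).
#' @param v12_const Constant diabatic coupling, used for 1-D avoided
#'   crossing studies.
#' @param q_to_deg Output mapping of `q` to the wag angle `delta_op`
#'   (degrees per unit q).
#' @return List of class `"isodyn_fssh_hamiltonian"`.
#' @export
fssh_hamiltonian <- function(w1 = 1, w2 = 1, de = 0.8,
                             mq = 100, wq = 2 * pi / 40,
                             itheta = 500, lam = 0.2, v12_const = 0,
                             q_to_deg = 30) {
  structure(as.list(environment()), class = "isodyn_fssh_hamiltonian")
}

# diabatic matrix elements and gradients at (theta, q)
.fssh_pot <- function(h, theta, q) {
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  harm <- 0.5 * h$mq * h$wq^2 * q^2
  v11 <- 0.5 * h$w1 * (1 - c2) + harm
  v22 <- h$de + 0.5 * h$w2 * (1 + c2) + harm
  v12 <- h$lam * q + h$v12_const
  dv11 <- c(h$w1 * s2, h$mq * h$wq^2 * q)
  dv22 <- c(-h$w2 * s2, h$mq * h$wq^2 * q)
  dv12 <- c(0, h$lam)
  d <- (v11 - v22) / 2
  s <- (v11 + v22) / 2
  r <- sqrt(d^2 + v12^2)
  dd <- (dv11 - dv22) / 2
  ds <- (dv11 + dv22) / 2
  dr <- if (r < 1e-14) ds * 0 else (d * dd + v12 * dv12) / r
  phi <- 0.5 * atan2(v12, d)
  # nonadiabatic coupling vector d12 = grad(phi)
  d12 <- if (r < 1e-14) c(0, 0) else
    0.5 * (d * dv12 - v12 * dd) / r^2
  list(e = c(s - r, s + r), grad = rbind(ds - dr, ds + dr),
       phi = phi, d12 = d12, gap = 2 * r)
}

#' Propagate one surface-hopping trajectory
#'
#' @param h A [fssh_hamiltonian()].
#' @param init List with `x = c(theta, q)` (radians, dimensionless),
#'   `v = c(vtheta, vq)` and optionally `surface` (1 lower, 2 upper;
#'   default 2).
#' @param dt_nuc Nuclear time step in fs (must be at most 0.5).
#' @param horizon Propagation length in fs.
#' @param seed Integer seed for the hopping random numbers.
#' @param n_sub Electronic substeps per nuclear step (default 20).
#' @param decoherence_c Kinetic-energy constant of the energy-based
#'   decoherence time (default 0.1 model energy units); `NA` disables
#'   decoherence.
#' @param record_every Record a frame every this many fs (default 1).
#' @param energy_tol Allowed total-energy drift between hops (model energy
#'   units) before an integration error is raised (default 1e-3).
#' @return List: `trajectory` (a [trajectory()] on the 6-atom embedding
#'   with theta mapped to the twist and q to the wag), `frames` tibble
#'   (`time`, `theta`, `q`, `surface`, `energy`, `norm`), `n_hops`,
#'   `n_frustrated`, `max_energy_drift`, `max_norm_error`.
#' @export
fssh_trajectory <- function(h, init, dt_nuc = 0.25, horizon = 200,
                            seed = 1, n_sub = 20, decoherence_c = 0.1,
                            record_every = 1, energy_tol = 1e-3) {
  stopifnot(dt_nuc <= 0.5, dt_nuc > 0)
  set.seed(seed)
  m <- c(h$itheta, h$mq)
  x <- init$x
  v <- init$v
  surf <- init$surface %||% 2L
  cc <- c(0i, 0i)
  cc[surf] <- 1 + 0i
  pot <- .fssh_pot(h, x[1], x[2])
  n_steps <- ceiling(horizon / dt_nuc)
  rec_stride <- max(1L, round(record_every / dt_nuc))
  n_rec <- floor(n_steps / rec_stride) + 1L
  rec <- matrix(NA_real_, n_rec, 6)
  colnames(rec) <- c("time", "theta", "q", "surface", "energy", "norm")
  e_ref <- sum(0.5 * m * v^2) + pot$e[surf]
  rec[1, ] <- c(0, x, surf, e_ref, 1)
  ri <- 1L
  n_hops <- 0L; n_frustrated <- 0L
  max_drift <- 0; max_norm_err <- 0

  for (step in seq_len(n_steps)) {
    acc <- -pot$grad[surf, ] / m
    x_new <- x + v * dt_nuc + 0.5 * acc * dt_nuc^2
    pot_new <- .fssh_pot(h, x_new[1], x_new[2])
    acc_new <- -pot_new$grad[surf, ] / m
    v <- v + 0.5 * (acc + acc_new) * dt_nuc

    # finite-difference overlap coupling; phi is defined modulo pi
    dphi <- pot_new$phi - pot$phi
    dphi <- dphi - pi * round(dphi / pi)
    sigma12 <- sin(dphi) / dt_nuc     # <u1(t)|u2(t+dt)> / dt

    # electronic propagation with interpolated energies
    hsub <- dt_nuc / n_sub
    g_accum <- 0
    other <- 3L - surf
    for (ss in seq_len(n_sub)) {
      f <- (ss - 0.5) / n_sub
      e_mid <- (1 - f) * pot$e + f * pot_new$e
      cc <- cc * exp(-1i * e_mid * (hsub / 2))
      a <- sigma12 * hsub
      c1 <- cos(a) * cc[1] - sin(a) * cc[2]
      c2 <- sin(a) * cc[1] + cos(a) * cc[2]
      cc <- c(c1, c2)
      cc <- cc * exp(-1i * e_mid * (hsub / 2))
      # fewest-switches flux out of the active state
      sig_ab <- if (surf == 1L) sigma12 else -sigma12
      rho_aa <- Mod(cc[surf])^2
      if (rho_aa > 1e-12) {
        g_accum <- g_accum +
          max(0, 2 * sig_ab * Re(Conj(cc[surf]) * cc[other]) * hsub / rho_aa)
      }
    }
    max_norm_err <- max(max_norm_err, abs(sum(Mod(cc)^2) - 1))

    if (runif(1) < g_accum) {
      # attempt a hop; rescale velocity along the coupling direction
      d <- pot_new$d12
      if (sqrt(sum(d^2)) < 1e-14) d <- c(1, 0)
      gap <- pot_new$e[other] - pot_new$e[surf]
      A <- 0.5 * sum(m * d^2)
      B <- sum(m * v * d)
      disc <- B^2 - 4 * A * gap
      if (disc >= 0) {
        gam <- if (B >= 0) (B - sqrt(disc)) / (2 * A)
               else (B + sqrt(disc)) / (2 * A)
        v <- v - gam * d
        surf <- other
        other <- 3L - surf
        n_hops <- n_hops + 1L
        e_ref <- sum(0.5 * m * v^2) + pot_new$e[surf]
      } else {
        # frustrated hop: reverse the velocity component along d
        vd <- sum(m * v * d) / sum(m * d * d)
        v <- v - 2 * vd * d
        n_frustrated <- n_frustrated + 1L
        e_ref <- sum(0.5 * m * v^2) + pot_new$e[surf]
      }
    }

    # energy-based decoherence damping of the inactive amplitude
    if (!is.na(decoherence_c)) {
      ekin <- sum(0.5 * m * v^2)
      de_gap <- abs(pot_new$e[other] - pot_new$e[surf])
      if (de_gap > 1e-12 && ekin > 1e-12) {
        tau_d <- (1 / de_gap) * (1 + decoherence_c / ekin)
        cc[other] <- cc[other] * exp(-dt_nuc / tau_d)
        pa <- Mod(cc[surf])^2
        if (pa > 1e-300) {
          cc[surf] <- cc[surf] *
            sqrt(max(0, 1 - Mod(cc[other])^2) / pa)
        }
      }
    }

    x <- x_new
    pot <- pot_new
    e_tot <- sum(0.5 * m * v^2) + pot$e[surf]
    max_drift <- max(max_drift, abs(e_tot - e_ref))
    if (step %% rec_stride == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(step * dt_nuc, x, surf,
                     e_tot, sum(Mod(cc)^2))
    }
  }
  if (max_drift > energy_tol) {
    abort(sprintf("energy drift %.3e exceeds tolerance %.1e", max_drift,
                  energy_tol), class = "isodyn_integration_error")
  }
  frames <- as_tibble(rec[seq_len(ri), , drop = FALSE])
  alpha <- rad2deg(frames$theta)
  delta <- frames$q * h$q_to_deg
  traj <- trajectory(sprintf("fssh%06d", seed),
                     embed_xyz(alpha, alpha - delta),
                     frames$time,
                     states = ifelse(frames$surface == 2, 1L, 0L),
                     meta = list(atom_labels = c("C", "C", "C", "C",
                                                 "H", "H")))
  list(trajectory = traj, frames = frames, n_hops = n_hops,
       n_frustrated = n_frustrated, max_energy_drift = max_drift,
       max_norm_error = max_norm_err)
}

#' Run a surface-hopping ensemble
#'
#' Samples initial conditions from a thermal (Gaussian) distribution on
#' the lower surface around the (pre-twisted) reactant minimum, promotes
#' them vertically to the upper surface, and propagates each trajectory.
#'
#' @param h A [fssh_hamiltonian()].
#' @param n Number of trajectories.
#' @param seed Base seed; trajectory `i` uses `seed * 1000 + i` for both
#'   sampling and hopping.
#' @param kt Thermal energy (model energy units; default 0.04, roughly
#'   room temperature on the model's scale).
#' @param pretwist Mean initial twist in radians (negative biases the
#'   rotation counterclockwise).
#' @param theta_sd Spread of the initial twist (radians).
#' @param ... Passed to [fssh_trajectory()] (`dt_nuc`, `horizon`, ...).
#' @return List: `ensemble` (an [ensemble()] on the 6-atom embedding) and
#'   `runs` (per-trajectory summaries from [fssh_trajectory()]).
#' @export
fssh_ensemble <- function(h, n, seed = 1, kt = 0.04,
                          pretwist = -0.18, theta_sd = 0.05, ...) {
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seed * 1000 + i
    set.seed(s)
    init <- list(
      x = c(rnorm(1, pretwist, theta_sd),
            rnorm(1, 0, sqrt(kt / (h$mq * h$wq^2)))),
      v = c(rnorm(1, 0, sqrt(kt / h$itheta)),
            rnorm(1, 0, sqrt(kt / h$mq))),
      surface = 2L
    )
    runs[[i]] <- fssh_trajectory(h, init, seed = s, ...)
  }
  trajs <- lapply(runs, function(r) r$trajectory)
  list(ensemble = ensemble(trajs, dihedral_map = fragment_dihedral_map(),
                           dt = 1),
       runs = runs)
}

#' Landau-Zener diabatic transition probability
#'
#' Closed-form single-passage probability
#' `exp(-2*pi*V12^2 / (v * |F1 - F2|))` (hbar = 1) for a linear crossing
#' traversed at velocity `v`, where `F1 - F2` is the diabatic slope
#' difference at the crossing.  Used as the independent oracle for the
#' 1-D high-velocity limit of the surface-hopping dynamics.
#'
#' @param v12 Diabatic coupling at the crossing.
#' @param speed Nuclear velocity through the crossing.
#' @param slope_diff Absolute difference of the diabatic slopes.
#' @return Probability in `[0, 1]`.
#' @export
landau_zener_prob <- function(v12, speed, slope_diff) {
  exp(-2 * pi * v12^2 / (abs(speed) * abs(slope_diff)))
}
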