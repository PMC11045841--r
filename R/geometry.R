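# Internal coordinates of the isomerizing ethylenic fragment and their
# finite-difference velocities.
#
# alpha    C1-C2-C3-C4 dihedral: the double-bond twist (reaction coordinate)
# beta     R1-C2-C3-R4 dihedral: the wag of the ethylenic substituents
# delta_op out-of-plane wag coordinate, alpha - beta
# tau      p-orbital overlap dihedral, alpha - 0.5*delta_op = (alpha+beta)/2;
#          tau = 0 at the cis reactant, -90 at the conical intersection and
#          -180 at the trans product for a counterclockwise rotation
# rho/gamma ring-inversion dihedrals of the five-membered rings
# bla      bond-length alternation (mean single minus mean double bond length)

#' Signed dihedral angle of four points
#'
#' Standard two-plane/atan2 construction with the IUPAC sign convention:
#' positive angles are clockwise rotations of the p1-p2 bond into the p3-p4
#' bond when viewed from p2 towards p3.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (positions in Angstrom).
#' @return Angle in degrees in the range (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12) abort("p2 and p3 coincide: dihedral undefined")
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    abort("collinear bonded triple: dihedral undefined")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

# dihedral over all frames of a coords array for an atom quadruple
.dihedral_series <- function(coords, quad) {
  n <- dim(coords)[1]
  vapply(seq_len(n), function(k) {
    dihedral_angle(coords[k, quad[1], ], coords[k, quad[2], ],
                   coords[k, quad[3], ], coords[k, quad[4], ])
  }, numeric(1))
}

#' Unwrap a wrapped angle series
#'
#' Adjusts each consecutive difference by multiples of 360 degrees so its
#' magnitude is below 180, leaving the first value unchanged.  Needed
#' because the counterclockwise rotation runs continuously through
#' 0 -> -90 -> -180 while raw dihedrals wrap into (-180, 180].
#'
#' @param x Angle series in degrees.
#' @return Unwrapped series in degrees.
#' @export
unwrap_deg <- function(x) {
  if (length(x) == 0) abort("cannot unwrap an empty series")
  if (length(x) == 1) return(x)
  # fold each consecutive difference into (-180, 180] and re-accumulate
  d <- diff(x)
  d <- d - 360 * ceiling((d - 180) / 360)
  x[1] + c(0, cumsum(d))
}

# forward-difference velocity on a (possibly irregular) time grid; the last
# entry is NA because no later frame exists
.forward_velocity <- function(x, times) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  c(diff(x) / diff(times), NA_real_)
}

.bla_series <- function(coords, bla_map) {
  bond_len <- function(pair) {
    sqrt(rowSums((coords[, pair[1], , drop = TRUE] -
                    coords[, pair[2], , drop = TRUE])^2))
  }
  singles <- rowMeans(vapply(bla_map$single, bond_len,
                             numeric(dim(coords)[1])))
  doubles <- rowMeans(vapply(bla_map$double, bond_len,
                             numeric(dim(coords)[1])))
  singles - doubles
}

#' Derive internal-coordinate time series for one trajectory
#'
#' Measures and unwraps the mapped dihedrals, forms the wag coordinate
#' `delta_op = alpha - beta` and the overlap dihedral
#' `tau = alpha - 0.5 * delta_op`, and attaches forward-difference
#' velocities over the actual frame spacing, so that
#' `d_tau = d_alpha - 0.5 * d_delta_op` holds identically at every frame.
#'
#' @param traj A [trajectory()].
#' @param dihedral_map Dihedral map (see [ensemble()]); must contain at
#'   least `alpha` and `beta`.
#' @return A tibble with one row per frame: `time`, `state`, the angle
#'   columns (`alpha`, `beta`, `delta_op`, `tau`, plus `rho`, `gamma`,
#'   `bla` when mapped) and their velocity columns prefixed `d_`
#'   (deg/fs, or Angstrom/fs for `bla`; `NA` on the last frame).
#' @export
derive_series <- function(traj, dihedral_map) {
  if (is.null(dihedral_map$alpha) || is.null(dihedral_map$beta)) {
    abort("dihedral_map must define at least `alpha` and `beta`")
  }
  nat <- n_atoms(traj)
  quads <- dihedral_map[intersect(names(dihedral_map),
                                  c("alpha", "beta", "rho", "gamma"))]
  bad <- unlist(quads)[unlist(quads) > nat | unlist(quads) < 1]
  if (length(bad)) abort("dihedral_map refers to atoms outside the trajectory")

  out <- tibble(time = traj$times, state = traj$states)
  for (nm in names(quads)) {
    out[[nm]] <- unwrap_deg(.dihedral_series(traj$coords, quads[[nm]]))
  }
  out$delta_op <- out$alpha - out$beta
  out$tau <- out$alpha - 0.5 * out$delta_op
  if (!is.null(dihedral_map$bla)) {
    out$bla <- .bla_series(traj$coords, dihedral_map$bla)
  }
  for (nm in setdiff(names(out), c("time", "state"))) {
    out[[paste0("d_", nm)]] <- .forward_velocity(out[[nm]], out$time)
  }
  out
}

#' Derive internal-coordinate series for every trajectory of an ensemble
#'
#' @param e An [ensemble()] with a dihedral map.
#' @param dihedral_map Optional override of the ensemble's map.
#' @return A tibble: the per-trajectory [derive_series()] outputs stacked
#'   with a leading `traj_id` column.
#' @export
ensemble_series <- function(e, dihedral_map = NULL) {
  map <- dihedral_map %||% e$dihedral_map
  if (is.null(map)) abort("no dihedral_map available")
  purrr::map_dfr(e$trajectories, function(tr) {
    dplyr::mutate(derive_series(tr, map), traj_id = tr$id, .before = 1)
  })
}
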