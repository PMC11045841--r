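#' Construct a single quantum-classical trajectory
#'
#' A trajectory is an ordered sequence of frames (Cartesian coordinates in
#' Angstrom on a regular femtosecond time grid) together with a per-frame
#' electronic-state label (0 = S0, 1 = S1, 2 = S2) and, optionally, a table
#' of explicit hop events.
#'
#' @param id Character identifier, unique within an ensemble.
#' @param coords Numeric array of dimension `c(n_frames, n_atoms, 3)`,
#'   coordinates in Angstrom.
#' @param times Numeric vector of frame times in fs, strictly increasing.
#' @param states Integer vector of per-frame electronic states in `0:2`.
#'   Defaults to all frames on S1.
#' @param hops Optional tibble with columns `frame`, `from`, `to`; `frame`
#'   is the 1-based index of the first frame on the new state.
#' @param meta Named list of free-form annotations (e.g. a system tag).
#' @return An object of class `"isodyn_trajectory"`.
#' @export
trajectory <- function(id, coords, times, states = NULL, hops = NULL,
                       meta = list()) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("`coords` must be an array of dimension c(n_frames, n_atoms, 3)")
  }
  n <- dim(coords)[1]
  if (length(times) != n) abort("`times` must have one entry per frame")
  if (n > 1 && any(diff(times) <= 0)) {
    abort(sprintf("frame times of trajectory '%s' are not strictly increasing", id))
  }
  if (is.null(states)) states <- rep(1L, n)
  states <- as.integer(states)
  if (length(states) != n || any(!states %in% 0:2)) {
    abort("`states` must give one value in 0:2 per frame")
  }
  if (!is.null(hops)) {
    hops <- as_tibble(hops)
    stopifnot(all(c("frame", "from", "to") %in% names(hops)))
    if (any(hops$from == hops$to)) abort("hop events must change the state")
    if (any(hops$frame < 1 | hops$frame > n)) {
      abort("hop frame index outside trajectory bounds")
    }
  }
  structure(
    list(id = as.character(id), coords = coords, times = as.numeric(times),
         states = states, hops = hops, meta = meta),
    class = "isodyn_trajectory"
  )
}

#' @export
print.isodyn_trajectory <- function(x, ...) {
  cat(sprintf("<isodyn_trajectory '%s': %d frames, %d atoms, t = %g..%g fs>\n",
              x$id, dim(x$coords)[1], dim(x$coords)[2],
              min(x$times), max(x$times)))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]

#' Construct a trajectory ensemble
#'
#' @param trajectories List of [trajectory()] objects sharing an atom count.
#' @param dihedral_map Named list mapping coordinate names to atom-index
#'   quadruples (1-based indices into the XYZ atom order).  Recognised names
#'   are `alpha`, `beta`, `rho`, `gamma`; an optional `bla` entry is a list
#'   with `single` and `double` elements, each a list of atom-index pairs
#'   (formal single and double bonds of the conjugated path).
#' @param dt Nominal frame spacing in fs (default 1).
#' @param atom_labels Optional character vector of element symbols.
#' @return An object of class `"isodyn_ensemble"`.
#' @export
ensemble <- function(trajectories, dihedral_map = NULL, dt = 1,
                     atom_labels = NULL) {
  if (dt <= 0) abort("`dt` must be positive")
  if (length(trajectories) > 0) {
    na <- vapply(trajectories, n_atoms, integer(1))
    if (length(unique(na)) > 1) {
      abort("all trajectories in an ensemble must share the atom count")
    }
    if (is.null(atom_labels)) {
      atom_labels <- trajectories[[1]]$meta$atom_labels %||%
        rep("C", na[[1]])
    }
  }
  ids <- vapply(trajectories, function(t) t$id, character(1))
  names(trajectories) <- ids
  structure(
    list(trajectories = trajectories, dihedral_map = dihedral_map,
         dt = dt, atom_labels = atom_labels),
    class = "isodyn_ensemble"
  )
}

#' @export
print.isodyn_ensemble <- function(x, ...) {
  cat(sprintf("<isodyn_ensemble: %d trajectories, %d atoms, dt = %g fs>\n",
              length(x$trajectories),
              if (length(x$trajectories)) n_atoms(x$trajectories[[1]]) else 0L,
              x$dt))
  invisible(x)
}

#' @export
length.isodyn_ensemble <- function(x) length(x$trajectories)

#' Default dihedral map for the 6-atom embedded fragment
#'
#' The synthetic generators emit a minimal 6-atom ethylenic fragment with
#' atom order C1, C2, C3, C4, R1, R4.  The double-bond twist `alpha` is the
#' C1-C2-C3-C4 dihedral and the substituent wag `beta` is R1-C2-C3-R4.
#'
#' @return Named list of 1-based atom-index quadruples.
#' @export
fragment_dihedral_map <- function() {
  list(alpha = c(1L, 2L, 3L, 4L), beta = c(5L, 2L, 3L, 6L))
}
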