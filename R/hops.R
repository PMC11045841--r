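# S1->S0 decay-point detection, decay observables and reactive/unreactive
# classification.
#
# Each trajectory contributes one decay point: the first S1->S0 transition
# (re-crossings are ignored).  Observables are evaluated on the last S1
# frame with backward-difference velocities, so that the decay velocity is
# defined before the ground-state force field acts.  Reactivity is read
# from the configuration reached at the end of the trajectory: the twist
# within +-tol of -180 deg marks the counterclockwise product (reactive),
# within +-tol of 0 the regenerated reactant (unreactive); anything else is
# left undecided and reported separately.

#' Locate the S1->S0 decay point of a trajectory
#'
#' Uses the per-frame state sequence when informative, otherwise an
#' explicit hop table; never infers a hop from geometry.
#'
#' @param traj A [trajectory()].
#' @return A one-row tibble `frame`, `from`, `to`, where `frame` is the
#'   1-based index of the first S0 frame.
#' @export
find_decay <- function(traj) {
  st <- traj$states
  # first frame where the state was 1 and becomes 0 (S2->S1 ignored)
  idx <- which(st[-length(st)] == 1L & st[-1] == 0L)
  if (length(idx) > 0) {
    return(tibble(frame = idx[1] + 1L, from = 1L, to = 0L))
  }
  if (length(unique(st)) == 1L && !is.null(traj$hops) &&
      nrow(traj$hops) > 0) {
    h <- traj$hops[traj$hops$from == 1L & traj$hops$to == 0L, , drop = FALSE]
    if (nrow(h) > 0) return(h[1, c("frame", "from", "to")])
  }
  abort(sprintf("trajectory '%s' has no S1->S0 decay", traj$id),
        class = "isodyn_no_decay")
}

#' Classify a decayed trajectory as reactive or unreactive
#'
#' @param end_alpha Unwrapped twist angle at the final frame, degrees.
#' @param tol Half-width of the classification windows, degrees
#'   (default 45, separating the reactant, crossing and product basins).
#' @return `"reactive"`, `"unreactive"` or `"undecided"`.  The comparison
#'   uses circular distance, so adding 360 degrees to the whole series does
#'   not change the label and both -180 and +180 mark the product.
#' @export
classify_outcome <- function(end_alpha, tol = 45) {
  dplyr::case_when(
    abs(ang_diff(end_alpha, -180)) <= tol ~ "reactive",
    abs(ang_diff(end_alpha, 0)) <= tol ~ "unreactive",
    TRUE ~ "undecided"
  )
}

#' Decay observables of one trajectory
#'
#' @param traj A [trajectory()].
#' @param series Output of [derive_series()] for `traj`.
#' @param hop Optional decay point (from [find_decay()]); located
#'   automatically when omitted.
#' @param tol Classification window half-width in degrees.
#' @return One-row tibble: `traj_id`, `hop_frame` (first S0 frame),
#'   `hop_time` (time of the last S1 frame, fs), angles
#'   `alpha_decay`, `tau_decay`, `delta_op_decay` (deg), backward-difference
#'   velocities `dtau_decay`, `dalpha_decay`, `ddelta_op_decay` (and
#'   `drho_decay` when `rho` is mapped; deg/fs), `end_alpha` (deg),
#'   `outcome`, and quality flags `short_tail` (fewer than 5 post-hop
#'   frames) and `velocity_defined` (FALSE when the hop is too early for a
#'   backward difference).
#' @export
decay_observables <- function(traj, series, hop = NULL, tol = 45) {
  hop <- hop %||% find_decay(traj)
  k <- hop$frame - 1L                 # last S1 frame
  if (k < 1L) abort("hop at the first frame: no S1 frame to evaluate")
  n <- nrow(series)
  back <- function(col) {
    if (k < 2L) return(NA_real_)
    (series[[col]][k] - series[[col]][k - 1L]) /
      (series$time[k] - series$time[k - 1L])
  }
  end_alpha <- series$alpha[n]
  tibble(
    traj_id = traj$id,
    hop_frame = hop$frame,
    hop_time = series$time[k],
    alpha_decay = series$alpha[k],
    tau_decay = series$tau[k],
    delta_op_decay = series$delta_op[k],
    dalpha_decay = back("alpha"),
    ddelta_op_decay = back("delta_op"),
    dtau_decay = back("tau"),
    drho_decay = if ("rho" %in% names(series)) back("rho") else NA_real_,
    end_alpha = end_alpha,
    outcome = classify_outcome(end_alpha, tol),
    short_tail = (n - hop$frame + 1L) < 5L,
    velocity_defined = k >= 2L
  )
}

#' Decay-point table of an ensemble
#'
#' Runs [derive_series()], [find_decay()] and [decay_observables()] over
#' every trajectory and stacks the per-trajectory records.  Trajectories
#' without an S1->S0 decay are excluded and counted in the
#' `n_no_decay` attribute (set `undecayed = "unreactive"` to count them as
#' unreactive records instead).
#'
#' @param e An [ensemble()] with a dihedral map.
#' @param tol Classification window half-width in degrees.
#' @param undecayed `"exclude"` (default) or `"unreactive"`.
#' @return A tibble of decay records (see [decay_observables()]) with
#'   attributes `n_no_decay` and `n_total`.
#' @export
hop_table <- function(e, tol = 45, undecayed = c("exclude", "unreactive")) {
  undecayed <- match.arg(undecayed)
  map <- e$dihedral_map %||% abort("ensemble has no dihedral_map")
  recs <- list()
  n_no_decay <- 0L
  for (tr in e$trajectories) {
    ser <- derive_series(tr, map)
    rec <- tryCatch(
      decay_observables(tr, ser, tol = tol),
      isodyn_no_decay = function(e) NULL
    )
    if (is.null(rec)) {
      n_no_decay <- n_no_decay + 1L
      if (undecayed == "unreactive") {
        rec <- tibble(traj_id = tr$id, hop_frame = NA_integer_,
                      hop_time = NA_real_, alpha_decay = NA_real_,
                      tau_decay = NA_real_, delta_op_decay = NA_real_,
                      dalpha_decay = NA_real_, ddelta_op_decay = NA_real_,
                      dtau_decay = NA_real_, drho_decay = NA_real_,
                      end_alpha = ser$alpha[nrow(ser)],
                      outcome = "unreactive", short_tail = TRUE,
                      velocity_defined = FALSE)
      }
    }
    if (!is.null(rec)) recs[[tr$id]] <- rec
  }
  out <- dplyr::bind_rows(recs)
  attr(out, "n_no_decay") <- n_no_decay
  attr(out, "n_total") <- length(e$trajectories)
  out
}
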