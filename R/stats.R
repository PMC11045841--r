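# Ensemble statistics: quantum efficiency, conditional fractions over the
# sign and amplitude of the decay velocity, decay-velocity histograms,
# decay-window summaries and survivor-averaged series.

#' Quantum-efficiency and decay-velocity condition table
#'
#' Computes, over the classified (reactive or unreactive) records, the
#' photoisomerization quantum efficiency `phi_iso` (fraction of reactive
#' trajectories) and the conditional fractions that relate reactivity to
#' the sign and amplitude of the overlap-dihedral velocity at decay:
#' the full-population fraction with `dtau_decay < 0`, the fraction of the
#' reactive population with `dtau_decay < 0`, the reactive fraction of the
#' negative-velocity population, and the same statistics for the
#' low-amplitude band (default `-0.8 < dtau_decay < 0` deg/fs) where the
#' sign condition loses predictive power.  An exact tie `dtau_decay == 0`
#' counts as non-negative.
#'
#' @param records Decay-record tibble from [hop_table()].
#' @param band Low-amplitude velocity band `(lo, hi)` in deg/fs.
#' @param conf Confidence level of the Wilson interval on `phi_iso`.
#' @return One-row tibble of counts, fractions and the Wilson interval;
#'   class `"isodyn_condition_table"`.  Fractions satisfy the law of total
#'   probability:
#'   `phi_iso = p_reactive_given_neg * frac_dtau_neg +
#'    p_reactive_given_pos * (1 - frac_dtau_neg)`.
#' @export
condition_table <- function(records, band = c(-0.8, 0), conf = 0.95) {
  cl <- records[records$outcome %in% c("reactive", "unreactive") &
                  records$velocity_defined, , drop = FALSE]
  if (nrow(cl) == 0) abort("no classified decay records")
  v <- cl$dtau_decay
  reactive <- cl$outcome == "reactive"
  neg <- v < 0
  in_band <- v > band[1] & v < band[2]
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  wi <- wilson_ci(sum(reactive), nrow(cl), conf)
  tibble(
    n_total = attr(records, "n_total") %||% nrow(records),
    n_classified = nrow(cl),
    n_reactive = sum(reactive),
    n_unreactive = sum(!reactive),
    n_excluded = (attr(records, "n_total") %||% nrow(records)) - nrow(cl),
    phi_iso = mean(reactive),
    phi_iso_lo = wi[1], phi_iso_hi = wi[2],
    frac_dtau_neg = mean(neg),
    p_neg_given_reactive = frac(sum(neg & reactive), sum(reactive)),
    p_reactive_given_neg = frac(sum(neg & reactive), sum(neg)),
    p_reactive_given_pos = frac(sum(!neg & reactive), sum(!neg)),
    band_lo = band[1], band_hi = band[2],
    frac_in_band_of_neg = frac(sum(in_band), sum(neg)),
    p_reactive_given_band = frac(sum(in_band & reactive), sum(in_band))
  ) -> out
  class(out) <- c("isodyn_condition_table", class(out))
  out
}

#' Decay-velocity histogram
#'
#' Bins the decay velocities of reactive and unreactive trajectories with
#' 1 deg/fs wide bins starting from -10, plus a finer inset around zero.
#' Values outside the coarse range are clipped into the end bins.
#'
#' @param records Decay-record tibble from [hop_table()].
#' @param width,start Coarse bin width and lower edge (deg/fs).
#' @param fine_width,fine_range Inset bin width and range (deg/fs).
#' @return A tibble with columns `scale` (`"coarse"` or `"fine"`), `lo`,
#'   `hi`, `mid`, `n_reactive`, `n_unreactive`; attribute `n_clipped`
#'   counts clipped values.
#' @export
velocity_histogram <- function(records, width = 1, start = -10,
                               fine_width = 0.2, fine_range = c(-1, 1)) {
  cl <- records[records$outcome %in% c("reactive", "unreactive") &
                  records$velocity_defined, , drop = FALSE]
  if (nrow(cl) == 0) abort("no records with a defined decay velocity")
  v <- cl$dtau_decay
  clipped <- sum(v < start | v >= -start)
  v_clip <- pmin(pmax(v, start), -start - width / 2)
  bin_counts <- function(vals, edges, keep) {
    idx <- findInterval(vals[keep], edges, rightmost.closed = FALSE)
    tabulate(idx, nbins = length(edges) - 1)
  }
  make <- function(edges, scale, vals, inside) {
    tibble(scale = scale, lo = edges[-length(edges)], hi = edges[-1],
           mid = (edges[-length(edges)] + edges[-1]) / 2,
           n_reactive = bin_counts(vals, edges,
                                   inside & cl$outcome == "reactive"),
           n_unreactive = bin_counts(vals, edges,
                                     inside & cl$outcome == "unreactive"))
  }
  coarse_edges <- seq(start, -start, by = width)
  fine_edges <- seq(fine_range[1], fine_range[2], by = fine_width)
  out <- dplyr::bind_rows(
    make(coarse_edges, "coarse", v_clip, rep(TRUE, length(v))),
    make(fine_edges, "fine", v, v >= fine_range[1] & v < fine_range[2])
  )
  attr(out, "n_clipped") <- clipped
  out
}

#' Decay-window summary (initial decay time and decay time length)
#'
#' @param records Decay-record tibble from [hop_table()].
#' @return One-row tibble: `idt` (first hop time, fs), `dtl` (spread
#'   between first and last hop, fs) and the robust 5th/95th-percentile
#'   variants `idt_robust`, `dtl_robust`.
#' @export
decay_window <- function(records) {
  ht <- records$hop_time[!is.na(records$hop_time)]
  if (length(ht) < 2) abort("decay window undefined for fewer than 2 hops")
  q <- unname(quantile(ht, c(0.05, 0.95), type = 7))
  tibble(idt = min(ht), dtl = max(ht) - min(ht),
         idt_robust = q[1], dtl_robust = q[2] - q[1])
}

#' Survivor-averaged time series
#'
#' Per-frame mean of a derived series over the trajectories still on the
#' selected electronic state at that time; decayed trajectories drop out
#' of the average, matching the convention of average curves drawn over
#' the undecayed population.  Bins with no surviving trajectory are
#' dropped, never zero-filled.
#'
#' @param series Stacked series tibble from [ensemble_series()].
#' @param what Column to average (e.g. `"alpha"`, `"d_tau"`,
#'   `"d_delta_op"`).
#' @param on_state State selecting survivors (default 1, i.e. S1; S2 counts
#'   as not-yet-decayed when `include_s2 = TRUE`).
#' @param include_s2 Whether S2 frames count as surviving (default TRUE).
#' @return Tibble `time`, `mean`, `n_surviving`.
#' @export
ensemble_average <- function(series, what, on_state = 1L,
                             include_s2 = TRUE) {
  if (!what %in% names(series)) {
    abort(sprintf("column '%s' not found in series", what))
  }
  keep <- if (include_s2 && on_state == 1L) series$state >= 1L
          else series$state == on_state
  series |>
    dplyr::filter(keep, !is.na(.data[[what]])) |>
    dplyr::summarise(mean = mean(.data[[what]]),
                     n_surviving = dplyr::n(), .by = "time") |>
    dplyr::arrange(.data$time)
}
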