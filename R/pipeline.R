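# End-to-end orchestration: ensemble -> derived series -> decay records ->
# condition statistics -> kinetic and oscillation fits, with optional
# delimited-text report output.

.as_ensemble_input <- function(source, seed) {
  if (inherits(source, "isodyn_ensemble")) {
    return(list(ensemble = source, ledger = NULL))
  }
  if (inherits(source, "isodyn_generator_config")) {
    return(generate_ensemble(source, seed = seed))
  }
  if (is.character(source) && length(source) == 1) {
    if (source %in% c("rh_like", "naip_like", "naip_gas_like")) {
      return(generate_ensemble(preset_config(source), seed = seed))
    }
    return(list(ensemble = read_ensemble(source), ledger = NULL))
  }
  abort("unsupported pipeline source")
}

#' Run the full trajectory-ensemble analysis
#'
#' Derives internal-coordinate series, locates and classifies decay
#' points, and computes the quantum-efficiency condition table, the
#' decay-velocity histogram, the decay window, the S1 population curve
#' with its lifetime fit, the promoter-velocity sinusoid fit (on the
#' survivor-averaged wag velocity `-0.5 * d_delta_op`) and the
#' twist decomposition.
#'
#' @param source An [ensemble()], a [generator_config()], a preset name
#'   (`"rh_like"`, `"naip_like"`, `"naip_gas_like"`) or a path readable by
#'   [read_ensemble()].
#' @param seed Seed used when `source` generates data.
#' @param tol Classification window half-width (degrees).
#' @param band Low-amplitude velocity band (deg/fs).
#' @param undecayed Treatment of undecayed trajectories (see
#'   [hop_table()]).
#' @param wag_period_hint Period hint (fs) for oscillation fits.
#' @param survivor_min Fraction of the ensemble that must survive for a
#'   time bin to enter averaged series used in fits (default 0.25).
#' @param out_dir Optional directory for delimited-text outputs.
#' @return Object of class `"isodyn_report"`: a list with elements
#'   `ensemble`, `series`, `records`, `condition`, `histogram`, `window`,
#'   `population`, `lifetime`, `promoter_fit`, `alpha_decomposition`,
#'   `mean_decay_time`, `params`.
#' @export
run_pipeline <- function(source, seed = 1, tol = 45, band = c(-0.8, 0),
                         undecayed = c("exclude", "unreactive"),
                         wag_period_hint = 40, survivor_min = 0.25,
                         out_dir = NULL) {
  undecayed <- match.arg(undecayed)
  inp <- .as_ensemble_input(source, seed)
  e <- inp$ensemble
  if (is.null(e$dihedral_map) && length(e$trajectories) > 0 &&
      dim(e$trajectories[[1]]$coords)[2] == 6) {
    e$dihedral_map <- fragment_dihedral_map()
  }
  series <- ensemble_series(e)
  records <- hop_table(e, tol = tol, undecayed = undecayed)
  cond <- condition_table(records, band = band)
  hist <- velocity_histogram(records)
  win <- decay_window(records)
  pop <- s1_population(e)
  lifetime <- tryCatch(fit_lifetime(pop),
                       isodyn_fit_failure = function(err) NULL)

  n_tot <- length(e$trajectories)
  avg_wag <- ensemble_average(series, "d_delta_op") |>
    dplyr::filter(.data$n_surviving >= survivor_min * n_tot) |>
    dplyr::mutate(mean = -0.5 * .data$mean)
  promoter_fit <- tryCatch(
    fit_sinusoid(avg_wag, period_hint = wag_period_hint),
    error = function(err) NULL)
  avg_alpha <- ensemble_average(series, "alpha") |>
    dplyr::filter(.data$n_surviving >= survivor_min * n_tot)
  decomp <- tryCatch(
    suppressWarnings(decompose_alpha(avg_alpha,
                                     period_hint = wag_period_hint,
                                     rms_warn = Inf)),
    error = function(err) NULL)

  rep <- structure(list(
    ensemble = e, ledger = inp$ledger, series = series, records = records,
    condition = cond, histogram = hist, window = win, population = pop,
    lifetime = lifetime, promoter_fit = promoter_fit,
    alpha_decomposition = decomp,
    mean_decay_time = mean(records$hop_time, na.rm = TRUE),
    params = list(seed = seed, tol = tol, band = band,
                  undecayed = undecayed,
                  wag_period_hint = wag_period_hint,
                  survivor_min = survivor_min)
  ), class = "isodyn_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.isodyn_report <- function(x, ...) {
  cond <- x$condition
  cat(sprintf(paste0("<isodyn_report: %d trajectories, %d classified | ",
                     "Phi_iso = %.3f [%.3f, %.3f] | IDT %.0f fs, ",
                     "DTL %.0f fs>\n"),
              cond$n_total, cond$n_classified, cond$phi_iso, cond$phi_iso_lo,
              cond$phi_iso_hi, x$window$idt, x$window$dtl))
  invisible(x)
}

#' Machine-readable key/value summary of a report
#'
#' @param x An `isodyn_report`.
#' @return Named list of scalar summary values (fractions as percentages).
#' @export
report_summary <- function(x) {
  cond <- x$condition
  out <- list(
    n_total = cond$n_total,
    n_classified = cond$n_classified,
    phi_iso_pct = 100 * cond$phi_iso,
    frac_dtau_neg_full_pct = 100 * cond$frac_dtau_neg,
    frac_dtau_neg_of_reactive_pct = 100 * cond$p_neg_given_reactive,
    frac_reactive_of_neg_pct = 100 * cond$p_reactive_given_neg,
    frac_band_of_neg_pct = 100 * cond$frac_in_band_of_neg,
    frac_reactive_of_band_pct = 100 * cond$p_reactive_given_band,
    idt_fs = x$window$idt,
    dtl_fs = x$window$dtl,
    mean_decay_time_fs = x$mean_decay_time
  )
  if (!is.null(x$lifetime)) {
    out$fitted_s1_lifetime_fs <- x$lifetime$lifetime
  }
  if (!is.null(x$promoter_fit) && !x$promoter_fit$flat) {
    out$promoter_period_fs <- x$promoter_fit$period
    out$promoter_amplitude_deg_fs <- x$promoter_fit$amplitude
  }
  if (!is.null(x$alpha_decomposition)) {
    out$alpha_drift_deg_fs <- x$alpha_decomposition$slope
  }
  out
}

#' Write the delimited-text report bundle
#'
#' @param x An `isodyn_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    w(x$records[setdiff(names(x$records), "series")], "hop_table.tsv"),
    w(as.data.frame(x$condition), "condition_table.tsv"),
    w(x$histogram, "velocity_histogram.tsv"),
    w(x$population, "population.tsv")
  )
  s <- report_summary(x)
  p <- file.path(out_dir, "report.txt")
  writeLines(sprintf("%s=%.6g", names(s), unlist(s)), p)
  invisible(c(paths, p))
}

#' Compare two analysis reports
#'
#' Side-by-side quantum-efficiency and timing statistics for two runs
#' (e.g. a rhodopsin-like and a rotor-like ensemble), with the difference
#' and a combined 95% interval on the quantum-efficiency difference.
#'
#' @param a,b `isodyn_report` objects.
#' @param labels Column labels.
#' @return Tibble `quantity`, `<label_a>`, `<label_b>`, `difference`.
#'   Attribute `phi_diff_ci` carries the interval on the
#'   quantum-efficiency difference.
#' @export
compare_runs <- function(a, b, labels = c("a", "b")) {
  sa <- report_summary(a)
  sb <- report_summary(b)
  keys <- union(names(sa), names(sb))
  out <- tibble(
    quantity = keys,
    !!labels[1] := vapply(keys, function(k) sa[[k]] %||% NA_real_,
                          numeric(1)),
    !!labels[2] := vapply(keys, function(k) sb[[k]] %||% NA_real_,
                          numeric(1))
  )
  out$difference <- out[[labels[1]]] - out[[labels[2]]]
  ca <- a$condition; cb <- b$condition
  se <- function(cc) (cc$phi_iso_hi - cc$phi_iso_lo) / (2 * 1.96)
  d <- ca$phi_iso - cb$phi_iso
  half <- 1.96 * sqrt(se(ca)^2 + se(cb)^2)
  attr(out, "phi_diff_ci") <- c(d - half, d + half)
  out
}
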