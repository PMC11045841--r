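# Diagnostic figures.  Colour convention throughout: red = reactive,
# blue = unreactive, grey = undecided/excluded.

.outcome_colours <- c(reactive = "#c0392b", unreactive = "#2d6fb4",
                      undecided = "grey55")

#' Spaghetti plot of twist evolution with decay points
#'
#' Twist angle against time for every trajectory, coloured by outcome,
#' with circles at the decay points.
#'
#' @param series Stacked series from [ensemble_series()].
#' @param records Decay records from [hop_table()].
#' @return A ggplot object.
#' @export
plot_alpha_traces <- function(series, records) {
  dat <- dplyr::left_join(series,
                          records[, c("traj_id", "outcome", "hop_time",
                                      "alpha_decay")],
                          by = "traj_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$alpha,
                                    group = .data$traj_id,
                                    colour = .data$outcome)) +
    ggplot2::geom_line(linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_point(data = records,
                        ggplot2::aes(x = .data$hop_time,
                                     y = .data$alpha_decay,
                                     colour = .data$outcome),
                        inherit.aes = FALSE, shape = 1, size = 1.8) +
    ggplot2::scale_colour_manual(values = .outcome_colours,
                                 na.value = "grey80") +
    ggplot2::labs(x = "time (fs)", y = "twist angle alpha (deg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Decay-velocity histogram figure
#'
#' @param hist Output of [velocity_histogram()].
#' @param scale `"coarse"` or `"fine"`.
#' @return A ggplot object (stacked reactive/unreactive counts).
#' @export
plot_velocity_histogram <- function(hist, scale = c("coarse", "fine")) {
  scale <- match.arg(scale)
  dat <- hist |>
    dplyr::filter(.data$scale == !!scale) |>
    tidyr::pivot_longer(c("n_reactive", "n_unreactive"),
                        names_to = "outcome", values_to = "count") |>
    dplyr::mutate(outcome = sub("n_", "", .data$outcome))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid, y = .data$count,
                                    fill = .data$outcome)) +
    ggplot2::geom_col(width = dat$hi[1] - dat$lo[1]) +
    ggplot2::scale_fill_manual(values = .outcome_colours) +
    ggplot2::labs(x = "d tau/dt at decay (deg/fs)", y = "trajectories",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.isodyn_lifetime_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$s1_fraction),
                        size = 0.6, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#c0392b") +
    ggplot2::labs(x = "time (fs)", y = "S1 population fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.isodyn_sinusoid_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value),
                        size = 0.6, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2d6fb4") +
    ggplot2::labs(x = "time (fs)", y = "value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.isodyn_alpha_decomposition <- function(object, ...) {
  dat <- object$curve |>
    dplyr::mutate(linear = object$intercept + object$slope * .data$time)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value),
                        size = 0.6, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$linear), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#c0392b") +
    ggplot2::labs(x = "time (fs)", y = "average twist (deg)") +
    ggplot2::theme_minimal()
}
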