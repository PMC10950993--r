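traj_long <- function(x) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = c("n_healthy", "n_cancer", "n_mutant"),
                      names_to = "type", names_prefix = "n_",
                      values_to = "count")
}

type_scale <- function() {
  ggplot2::scale_colour_manual(
    values = c(healthy = "#4575b4", cancer = "#d73027", mutant = "#7b3294"),
    aesthetics = c("colour", "fill"))
}

#' Plot a single trajectory
#'
#' @param object A `moran_trajectory` or `expected_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moran_trajectory <- function(object, ...) {
  ggplot2::ggplot(traj_long(object),
                  ggplot2::aes(.data$division_index, .data$count,
                               colour = .data$type)) +
    ggplot2::geom_line() +
    type_scale() +
    ggplot2::labs(x = "cell divisions", y = "cells", colour = NULL)
}

#' @rdname autoplot.moran_trajectory
#' @export
autoplot.expected_trajectory <- autoplot.moran_trajectory

#' Plot an ensemble mean with a +/- 1 SD ribbon
#'
#' @param object A `moran_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moran_ensemble <- function(object, ...) {
  s <- object$summary |>
    tidyr::pivot_longer(-dplyr::any_of(c("division_index", "time_hours")),
                        names_to = c(".value", "type"), names_sep = "_")
  ggplot2::ggplot(s, ggplot2::aes(.data$division_index, .data$mean,
                                  colour = .data$type, fill = .data$type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = pmin(.data$mean + .data$sd,
                                                  object$N)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    type_scale() +
    ggplot2::labs(x = "cell divisions", y = "cells",
                  colour = NULL, fill = NULL)
}

#' Plot a fitted growth curve over the data
#'
#' @param object A `moran_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moran_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_days, .data$size)) +
    ggplot2::geom_line(data = fitted_curve(object), colour = "#d73027") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (days)", y = "tumour burden (proportion of N)")
}

#' Heatmap of a fixation-region scan
#'
#' @param scan Output of [scan_fixation_regions()].
#' @return A ggplot tile map of the majority classification.
#' @export
plot_fixation_regions <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(.data$f_m, .data$f_c,
                                     fill = .data$classification)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(mutant = "#7b3294",
                                          cancer = "#d73027",
                                          none = "white")) +
    ggplot2::labs(x = expression(f[m]), y = expression(f[c]), fill = NULL)
}

#' Per-strategy mean trajectories
#'
#' @param report A `strategy_report` from [compare_strategies()].
#' @return A ggplot faceted by strategy.
#' @export
plot_strategies <- function(report) {
  s <- report$summaries |>
    tidyr::pivot_longer(-dplyr::any_of(c("strategy", "division_index",
                                         "time_hours")),
                        names_to = c(".value", "type"), names_sep = "_")
  ggplot2::ggplot(s, ggplot2::aes(.data$division_index, .data$mean,
                                  colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~strategy) +
    type_scale() +
    ggplot2::labs(x = "cell divisions", y = "mean cells", colour = NULL)
}
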