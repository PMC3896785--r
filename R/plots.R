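#' Plot the step-response trajectory
#'
#' Output (and optionally all node) trajectories on a log10 time axis, with
#' the pre-stimulus steady state marked.
#'
#' @param x A `step_response`.
#' @param all_nodes Show A and B alongside the output node. Default `FALSE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.step_response <- function(x, all_nodes = FALSE, ...) {
  traj <- x$trajectory
  if (is.null(traj)) stop("no trajectory to plot", call. = FALSE)
  long <- tidyr::pivot_longer(traj, -"time", names_to = "node",
                              values_to = "activity")
  if (!all_nodes) long <- long[long$node == utils::tail(names(traj), 1), ]
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$activity,
                                     colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = x$O1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (dimensionless)", y = "active fraction") +
    ggplot2::theme_minimal()
}

#' Distributions of solution parameter values
#'
#' Box plots of the log10 parameter values over the kinetic solutions, one
#' box per profiled parameter, with decade value-class boundaries drawn as
#' horizontal guides.
#'
#' @param x A `kinetic_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetic_screen <- function(x, ...) {
  model <- attr(x, "model")
  pars <- profiled_parameters(model)
  sol <- as_tibble(x)[!is.na(x$is_solution) & x$is_solution, pars]
  long <- tidyr::pivot_longer(sol, dplyr::everything(),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$parameter, log10(.data$value))) +
    ggplot2::geom_hline(yintercept = -3:2, colour = "grey85") +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "log10 parameter value") +
    ggplot2::theme_minimal()
}

#' Enrichment map of parameters by value class
#'
#' Tile map of -log10(p) per parameter and value class; significant cells
#' are outlined.
#'
#' @param x A `kinetic_enrichment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetic_enrichment <- function(x, ...) {
  tbl <- tidy(x)
  ggplot2::ggplot(tbl, ggplot2::aes(factor(.data$class), .data$parameter,
                                    fill = -log10(.data$p))) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = tbl[tbl$significant, ], fill = NA,
                       colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = "value class", y = NULL) +
    ggplot2::theme_minimal()
}

#' Association z-scores per motif parameter
#'
#' Paired bars of the sensitivity and precision Mann-Whitney z-scores, with
#' the critical value drawn as a dashed line.
#'
#' @param x A `kinetic_association`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetic_association <- function(x, ...) {
  long <- tidyr::pivot_longer(tidy(x)[c("parameter", "z_sensitivity",
                                        "z_precision")],
                              -"parameter", names_to = "functionality",
                              names_prefix = "z_", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(.data$parameter, .data$z,
                                     fill = .data$functionality)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = attr(x, "z_crit"),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Mann-Whitney z") +
    ggplot2::theme_minimal()
}
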