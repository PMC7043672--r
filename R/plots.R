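#' Plot a simulated trajectory
#'
#' Compartment densities over time on a log10 axis; densities below `floor`
#' are drawn at the floor so eradicated compartments stay visible.
#'
#' @param object A `copred_trajectory`.
#' @param floor Lower plotting floor (per ml), default 1.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.copred_trajectory <- function(object, floor = 1, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_h",
                              names_to = "compartment",
                              values_to = "density_per_ml")
  long$compartment <- factor(long$compartment, levels = copred_state_names())
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h,
                                     pmax(.data$density_per_ml, floor),
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "density (per ml)",
                  colour = "compartment")
}

#' Plot a synthetic predation-kinetics dataset
#'
#' Replicate plate counts per condition and population; censored samples are
#' drawn at the detection limit as open symbols.
#'
#' @param object A `copred_dataset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.copred_dataset <- function(object, ...) {
  limit <- attr(object, "design")$detection_limit %||% 10
  d <- as_tibble(object)
  d$density_plot <- ifelse(d$censored, limit, d$density_per_ml)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$density_plot,
                                  colour = .data$population,
                                  shape = .data$censored)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::geom_hline(yintercept = limit, linetype = "dotted") +
    ggplot2::labs(x = "time (h)", y = "density (per ml)")
}

#' Plot the progress of an ABC-SMC run
#'
#' Final-generation model frequencies per generation (stacked bars) with the
#' tolerance schedule annotated.
#'
#' @param object A `copred_smc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.copred_smc <- function(object, ...) {
  counts <- dplyr::count(object$particles, .data$generation, .data$model)
  ggplot2::ggplot(counts, ggplot2::aes(.data$generation, .data$n,
                                       fill = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "generation", y = "accepted particles", fill = "model",
      subtitle = paste("tolerances:",
                       paste(signif(object$generations$tolerance, 3),
                             collapse = " > "))
    )
}

#' Plot the outcome of an initial-density sweep
#'
#' Prey survival at the end of the experiment for each scaled population and
#' condition.
#'
#' @param object A `copred_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.copred_sweep <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$factor), .data$condition,
                                  fill = .data$prey_survival)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$population)) +
    ggplot2::labs(x = "initial-density scaling factor", y = "condition",
                  fill = "prey survive")
}
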