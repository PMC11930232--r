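# ggplot2 visualizations for the main result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot the head-tail angle programme of a synthetic C-start
#'
#' @param object a `cstart_kinematics`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cstart_kinematics <- function(object, ...) {
  df <- tibble::tibble(t_ms = object$times * 1000,
                       head_tail_angle = object$head_tail_angle,
                       stage = factor(object$stage,
                                      labels = c("C-bend", "counterbend",
                                                 "fast swim")[sort(unique(object$stage))]))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$head_tail_angle,
                                   colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "head-tail angle (deg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot power output and trajectory of an escape simulation
#'
#' Power per unit depth over time (raw and 1 ms smoothed), in the style
#' of a power/curvature diagnostic panel.
#'
#' @param object an `escape_sim`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.escape_sim <- function(object, ...) {
  tr <- object$trace
  dt <- tr$t[2] - tr$t[1]
  df <- tibble::tibble(t_ms = tr$t * 1000, P = tr$P,
                       P_smooth = smooth_trace(tr$P, dt, "power"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$P), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$P_smooth), colour = "red") +
    ggplot2::labs(x = "time (ms)", y = "power (W/m, raw and 1 ms mean)") +
    ggplot2::theme_minimal()
}

#' Plot a viscosity sweep summary
#'
#' Mean power, total energy and cost of transport versus viscosity, with
#' the fitted regression lines.
#'
#' @param object a `sweep_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  tbl <- object$table
  long <- tidyr::pivot_longer(
    tbl[, c("mu_mPas", "mean_power_W", "E_J", "CoT_J_m")],
    -"mu_mPas", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$mu_mPas, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "viscosity (mPa s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a midline
#'
#' @param x a `midline`.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_midline <- function(x, ...) {
  df <- tibble::tibble(x_mm = x[, 1], y_mm = x[, 2])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
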