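#' Plot methods
#'
#' ggplot2 visualizations for the package's result types: fitted rate curves
#' over the data, double-reciprocal diagnostics, progress curves, effector
#' titration replots and recovery distributions.
#'
#' @param object,x the object to plot.
#' @param ... unused.
#' @return a ggplot.
#' @name nadkin-plots
NULL

#' @rdname nadkin-plots
#' @method autoplot kin_fit
#' @export
autoplot.kin_fit <- function(object, ...) {
  d <- object$data
  if (inherits(object, "ic50_fit")) {
    grid <- tibble::tibble(I_uM = seq(0, max(d$I_uM), length.out = 200))
    grid$activity <- fractional_activity(grid$I_uM, object$params)
    return(ggplot2::ggplot(d, ggplot2::aes(x = .data$I_uM, y = .data$activity)) +
             ggplot2::geom_point() +
             ggplot2::geom_line(data = grid, colour = "steelblue") +
             ggplot2::labs(x = "inhibitor (µM)", y = "fractional activity",
                           title = sprintf("IC50 = %.3g µM", object$params$ic50)))
  }
  I_levels <- if ("I_uM" %in% names(d)) sort(unique(d$I_uM)) else 0
  grid <- tidyr::expand_grid(
    S_uM = exp(seq(log(min(d$S_uM)), log(max(d$S_uM)), length.out = 200)),
    I_uM = I_levels)
  grid$rate_mU_mg <- eval_rate_law(grid$S_uM, object$params, I = grid$I_uM)
  if (!"I_uM" %in% names(d)) d$I_uM <- 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$S_uM, y = .data$rate_mU_mg,
                                  colour = factor(.data$I_uM))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "substrate (µM)", y = "rate (mU/mg)",
                  colour = "inhibitor (µM)",
                  title = paste("fitted", object$model))
}

#' @rdname nadkin-plots
#' @method autoplot time_course
#' @export
autoplot.time_course <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_min",
                              names_to = "series", values_to = "uM")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$uM,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "concentration (µM)")
}

#' @rdname nadkin-plots
#' @method autoplot competition_analysis
#' @export
autoplot.competition_analysis <- function(object, ...) {
  m <- tidyr::pivot_longer(object$maxima, c("Kia", "V_opt"),
                           names_to = "quantity", values_to = "value")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$effector_uM, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.5) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "effector (µM)", title = object$verdict)
}

#' @rdname nadkin-plots
#' @method autoplot recovery_study
#' @export
autoplot.recovery_study <- function(object, ...) {
  est <- dplyr::filter(object$estimates, !.data$censored)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = sprintf("parameter recovery (%d sims, CV %.2g)",
                                  object$n_sims, object$cv))
}

#' Double-reciprocal plot
#'
#' @param data an initial-rate data frame (see [double_reciprocal()]).
#' @return a ggplot of 1/rate against 1/S with per-inhibitor-level OLS
#'   lines.
#' @export
plot_double_reciprocal <- function(data) {
  dr <- double_reciprocal(data)
  ggplot2::ggplot(dr$points, ggplot2::aes(x = .data$inv_S, y = .data$inv_rate,
                                          colour = factor(.data$I_uM))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = dr$lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = factor(.data$I_uM))) +
    ggplot2::labs(x = "1/S (µM⁻¹)", y = "1/v (mg/mU)",
                  colour = "inhibitor (µM)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
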