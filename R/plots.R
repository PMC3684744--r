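#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed against cross-validated predictions
#'
#' Scatter of observed transformed dispersal values against per-species
#' mean cross-validated predictions with their standard errors, the
#' calibration regression line, and the 1:1 line for reference.
#'
#' @param object A tibble from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_predictions
#' @export
autoplot.cv_predictions <- function(object, ...) {
  plot_cv(object)
}

#' @rdname autoplot.cv_predictions
#' @param cv A tibble from [cross_validate()].
#' @export
plot_cv <- function(cv, ...) {
  cv <- cv[!is.na(cv$pred_mean), ]
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$pred_mean, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$pred_mean - .data$pred_se,
                   xmax = .data$pred_mean + .data$pred_se),
      height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::labs(x = "mean cross-validated prediction",
                  y = "observed (transformed scale)") +
    ggplot2::theme_minimal()
}

#' Plot a model-selection AICc profile
#'
#' Dot plot of the stage-two candidate models within a given AICc window,
#' showing their AICc difference from the best model and their R-squared;
#' the retained model is highlighted.
#'
#' @param object A `syndrome_selection`.
#' @param max_delta Show models within this AICc window (default 6).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot syndrome_selection
#' @export
autoplot.syndrome_selection <- function(object, max_delta = 6, ...) {
  tab <- dplyr::filter(object$stage2, .data$delta_aicc <= max_delta)
  chosen_label <- if (nrow(object$chosen$terms))
    paste(object$chosen$terms$label, collapse = " + ") else "1"
  tab$chosen <- tab$label == chosen_label
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta_aicc, y = .data$r2,
                                    colour = .data$chosen)) +
    ggplot2::geom_vline(xintercept = object$delta, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = expression(Delta * "AICc"), y = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' Plot an R-squared partition
#'
#' @param object An `r2_partition`.
#' @param ... Unused.
#' @return A ggplot of per-term contributions.
#' @method autoplot r2_partition
#' @export
autoplot.r2_partition <- function(object, ...) {
  tab <- dplyr::arrange(object$contributions, .data$contribution)
  tab$label <- factor(tab$label, levels = tab$label)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$contribution, y = .data$label)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = expression("contribution to " * R^2), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot predicted and observed dispersal distributions
#'
#' Kernel-density curves of the natural-scale predictions and (when
#' present) observations, the display used to compare the inferred
#' distribution of dispersal ability with the measured one.
#'
#' @param object A `dispersal_summary` from [summarize_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dispersal_summary
#' @export
autoplot.dispersal_summary <- function(object, ...) {
  ggplot2::ggplot(object$densities,
                  ggplot2::aes(x = .data$x, y = .data$density,
                               colour = .data$group,
                               linetype = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "dispersal value (natural scale)", y = "density",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
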