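#' Plot a loess calibration curve
#'
#' Smoothed observed EP proportion against predicted risk, with the
#' pointwise confidence band and the 45-degree line of perfect
#' calibration.
#'
#' @param object A `pul_calibration_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pul_calibration_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted probability of EP",
                  y = "Observed proportion of EP",
                  title = "Calibration curve") +
    ggplot2::theme_minimal()
}

#' Plot a decision curve
#'
#' Net benefit of the model against the treat-all and treat-none default
#' strategies over the threshold grid.
#'
#' @param object A `pul_decision_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pul_decision_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("nb_model", "nb_all", "nb_none"),
                            names_to = "strategy", values_to = "nb")
  df$strategy <- factor(df$strategy, levels = c("nb_model", "nb_all",
                                                "nb_none"),
                        labels = c("model", "treat all", "treat none"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                   colour = .data$strategy,
                                   linetype = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(
      ylim = c(-0.05, max(df$nb, attr(object, "prevalence")) + 0.02)) +
    ggplot2::labs(x = "High-risk threshold probability",
                  y = "Net benefit (per patient)",
                  title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of predicted EP risk
#'
#' @inheritParams roc_auc
#' @return A ggplot of the empirical ROC curve.
#' @export
plot_roc <- function(data, score, truth) {
  pts <- roc_points(data, {{ score }}, {{ truth }})
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "Sensitivity",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}
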