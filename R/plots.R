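#' Predicted-versus-observed plot
#'
#' @param residuals The `residuals` tibble from [evaluate_model()].
#' @return A ggplot with the identity line.
#' @export
plot_predictions <- function(residuals) {
  ggplot2::ggplot(residuals, ggplot2::aes(x = .data$label,
                                          y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "labeled pKa", y = "predicted pKa") +
    ggplot2::theme_minimal()
}

#' Ablation / baseline result plots
#'
#' `plot_ablation()` draws the per-condition median MAE of [cmd_ablate()];
#' `plot_baselines()` the algorithm-by-featurization grid of
#' [baseline_grid()].
#'
#' @param results The respective result tibble.
#' @return A ggplot object.
#' @export
plot_ablation <- function(results) {
  results$condition <- factor(results$condition,
                              levels = rev(results$condition))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$median_mae,
                                        y = .data$condition)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "median test MAE (pKa units)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ablation
#' @export
plot_baselines <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$features, y = .data$mae,
                                        fill = .data$algo)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "test MAE (pKa units)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Attenuation-decay plot
#'
#' Predicted versus planted pKa-shift magnitude as a function of substituent
#' distance (see [attenuation_profile()]), on a log scale where geometric
#' decay is a straight line.
#'
#' @param profile Result of [attenuation_profile()].
#' @return A ggplot object.
#' @export
plot_attenuation <- function(profile) {
  long <- tidyr::pivot_longer(profile[, c("distance", "mean_abs_shift",
                                          "mean_abs_true")],
                              -"distance", names_to = "which",
                              values_to = "shift")
  long$which <- ifelse(long$which == "mean_abs_shift", "model", "planted")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance, y = .data$shift,
                                     colour = .data$which)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "substituent distance (bonds - 1)",
                  y = "mean |pKa shift|", colour = NULL) +
    ggplot2::theme_minimal()
}
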