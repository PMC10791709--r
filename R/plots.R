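#' Plot a ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC %.2f (95%% CI %.2f-%.2f)",
                      object$auc, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot a Bland-Altman agreement diagram
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "indianred") +
    ggplot2::labs(x = "Mean of paired scores", y = "Difference",
                  title = sprintf("Bias %.3f, LoA [%.3f, %.3f]",
                                  object$bias, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Plot per-slice severity tracks
#'
#' Predicted and/or true slice severities along the z axis, one panel per
#' lung side.
#'
#' @param track A ten-degree `slice_track` (predictions).
#' @param truth Optional second track drawn for comparison.
#' @return A ggplot.
#' @export
plot_slice_track <- function(track, truth = NULL) {
  df <- dplyr::mutate(as_tibble(track), source = "predicted")
  if (!is.null(truth))
    df <- dplyr::bind_rows(df, dplyr::mutate(as_tibble(truth),
                                             source = "truth"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice_index, y = .data$label,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~side) +
    ggplot2::ylim(0, 10) +
    ggplot2::labs(x = "Slice index (caudal to cranial)",
                  y = "Emphysema severity (0-10)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param model A trained `slice_regressor`.
#' @return A ggplot of train/validation loss per epoch and seed.
#' @export
plot_training_history <- function(model) {
  stopifnot(inherits(model, "slice_regressor"), !is.null(model$history))
  df <- tidyr::pivot_longer(model$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set,
                                   group = interaction(.data$seed, .data$set))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Weighted loss", colour = NULL) +
    ggplot2::theme_minimal()
}
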