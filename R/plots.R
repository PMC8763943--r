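#' Plot the ROC curve of an evaluation result
#'
#' @param object An `eval_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv", colour = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f, positive: %s)", object$auc, object$positive)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-run metrics of a repeated evaluation
#'
#' @param object An `eval_summary`.
#' @param ... Unused.
#' @return A ggplot with one point per run and metric, plus run means.
#' @export
autoplot.eval_summary <- function(object, ...) {
  long <- object$per_run |>
    pivot_longer(
      c("accuracy", "precision", "recall", "auc"),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7,
                         colour = "#2166ac") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "black") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Value",
                  title = "LOOCV metrics across repeated runs") +
    ggplot2::theme_minimal()
}

#' Heatmap-style overview of a feature matrix
#'
#' @param object A `feature_matrix`.
#' @param max_features Show at most this many features (by variance).
#' @param ... Unused.
#' @return A ggplot tile plot, samples by features.
#' @export
autoplot.feature_matrix <- function(object, max_features = 50, ...) {
  vals <- fm_values(object)
  if (ncol(vals) > max_features) {
    keep <- order(apply(vals, 2, stats::var), decreasing = TRUE)[seq_len(max_features)]
    vals <- vals[, sort(keep), drop = FALSE]
  }
  long <- as_tibble(vals, rownames = "sample_id") |>
    pivot_longer(-"sample_id", names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$feature, y = .data$sample_id, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = fm_transform(object)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("%s features (%s)", fm_modality(object), fm_transform(object))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
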