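# ggplot2 visualisations of evaluation results and fitted ensembles.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve of an evaluation
#'
#' @param object A `ppi_eval` row from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_eval <- function(object, ...) {
  pts <- roc_points(attr(object, "labels"), attr(object, "scores"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2171b5", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Per-learner out-of-fold AUC of a stacked ensemble
#'
#' Bar chart of each first-level learner's out-of-fold AUC, coloured by
#' encoding, with the stacked ensemble's own out-of-fold AUC as a dashed
#' reference line.
#'
#' @param object A fitted `ppi_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_ensemble <- function(object, ...) {
  td <- tidy(object)
  ens <- glance(object)$oof_auc_ensemble
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$learner,
                                                      .data$oof_auc),
                                   y = .data$oof_auc,
                                   fill = .data$technique)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = ens, linetype = "dashed") +
    ggplot2::coord_flip(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = "Out-of-fold AUC",
                  title = "First-level learners vs stacked ensemble",
                  subtitle = sprintf("dashed line: ensemble AUC %.3f", ens)) +
    ggplot2::theme_minimal()
}
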