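# Evaluation metrics: confusion counts at a threshold, accuracy / recall /
# precision / F1, and rank-based AUC.

#' Confusion counts at a score threshold
#'
#' A pair is predicted interacting when its score is greater than or equal to
#' the threshold (a score exactly at the threshold counts as positive).
#'
#' @param labels 0/1 vector of true labels.
#' @param scores Numeric vector of predicted interaction scores.
#' @param threshold Decision threshold in `(0, 1)` (default 0.5).
#' @return A one-row tibble of class `ppi_confusion` with columns
#'   `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  assert_that(length(labels) > 0, "empty input")
  assert_that(length(labels) == length(scores),
              "`labels` and `scores` must have equal length")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0 or 1")
  assert_that(threshold > 0 && threshold < 1, "`threshold` must be in (0, 1)")
  pred <- as.integer(scores >= threshold)
  out <- tibble::tibble(
    TP = sum(pred == 1L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    TN = sum(pred == 0L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  )
  class(out) <- c("ppi_confusion", class(out))
  out
}

# a ratio that is defined as 0 (with a warning) when its denominator is 0
.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and `F1 = 2TP/(2TP+FP+FN)`. A metric whose denominator is
#' zero is reported as 0 with a warning.
#'
#' @param counts A `ppi_confusion` row (see [confusion_counts()]).
#' @return A one-row tibble with columns `accuracy`, `recall`, `precision`,
#'   `f1`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  tibble::tibble(
    accuracy = .safe_ratio(TP + TN, TP + TN + FP + FN, "accuracy"),
    recall = .safe_ratio(TP, TP + FN, "recall"),
    precision = .safe_ratio(TP, TP + FP, "precision"),
    f1 = .safe_ratio(2 * TP, 2 * TP + FP + FN, "F1")
  )
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties receiving half credit; identical to the area under the
#' ROC curve with trapezoidal tie handling.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores Numeric score vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  assert_that(length(labels) == length(scores),
              "`labels` and `scores` must have equal length")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predicted interaction scores against labels
#'
#' One-stop evaluation: confusion counts at the threshold, the four
#' threshold metrics and rank-based AUC, as a single tidy row. The raw
#' labels/scores are kept as attributes so [ggplot2::autoplot()] can draw the
#' ROC curve.
#'
#' @param data A data frame holding labels and scores.
#' @param label_col,score_col Column names (defaults `label`, `.pred`).
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble of class `ppi_eval` with columns `n`, `TP`, `FP`,
#'   `TN`, `FN`, `accuracy`, `recall`, `precision`, `f1`, `auc`.
#' @export
evaluate_predictions <- function(data, label_col = "label",
                                 score_col = ".pred", threshold = 0.5) {
  labels <- data[[label_col]]
  scores <- data[[score_col]]
  cc <- confusion_counts(labels, scores, threshold)
  out <- dplyr::bind_cols(tibble::tibble(n = length(labels)), cc,
                          classification_metrics(cc),
                          tibble::tibble(auc = auc_score(labels, scores)))
  attr(out, "labels") <- labels
  attr(out, "scores") <- scores
  attr(out, "threshold") <- threshold
  class(out) <- c("ppi_eval", class(tibble::tibble()))
  out
}

#' ROC curve coordinates
#'
#' @param labels 0/1 labels.
#' @param scores Numeric scores.
#' @return A tibble with columns `fpr`, `tpr`, ordered from (0,0) to (1,1).
#' @export
roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- as.integer(labels)[ord]
  scores <- scores[ord]
  # one ROC vertex per distinct score value
  keep <- c(diff(scores) != 0, TRUE)
  tp <- cumsum(labels)[keep]
  fp <- cumsum(1L - labels)[keep]
  tibble::tibble(fpr = c(0, fp / max(fp)), tpr = c(0, tp / max(tp)))
}
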