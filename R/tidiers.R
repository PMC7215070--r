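# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-learner summary of a stacked ensemble
#'
#' One row per first-level learner with its configuration and out-of-fold
#' AUC.
#'
#' @param x A fitted `ppi_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `learner`, `technique`, `heads`, `dense`,
#'   `oof_auc`.
#' @export
tidy.ppi_ensemble <- function(x, ...) {
  cfgs <- x$config$learners
  tibble::tibble(
    learner = x$meta_feature_names,
    technique = vapply(cfgs, function(l) l$technique, character(1)),
    heads = vapply(cfgs, function(l) l$h, integer(1)),
    dense = vapply(cfgs, function(l) paste(l$dense, collapse = "-"),
                   character(1)),
    oof_auc = unname(x$oof_auc)
  )
}

#' One-row summary of a stacked ensemble
#'
#' @param x A fitted `ppi_ensemble`.
#' @param ... Unused.
#' @return A tibble with ensemble-level facts: learner and fold counts,
#'   training size, out-of-fold ensemble AUC (meta-learner applied to the
#'   training meta-features), meta iterations and final loss.
#' @export
glance.ppi_ensemble <- function(x, ...) {
  oof_pred <- predict(x$meta_model, x$meta)
  tibble::tibble(
    n_learners = length(x$fold_models),
    folds = x$config$K,
    n_train = length(x$labels),
    oof_auc_best_single = max(x$oof_auc),
    oof_auc_ensemble = auc_score(x$labels, oof_pred),
    meta_iters = x$meta_model$iters,
    meta_loss = utils::tail(x$meta_model$loss, 1)
  )
}

#' Tidy an evaluation row into metric/value pairs
#'
#' @param x A `ppi_eval` row from [evaluate_predictions()].
#' @param ... Unused.
#' @return A two-column tibble (`metric`, `value`).
#' @export
tidy.ppi_eval <- function(x, ...) {
  vals <- unlist(x[1, c("accuracy", "recall", "precision", "f1", "auc")])
  tibble::tibble(metric = names(vals), value = unname(vals))
}
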