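# Stacked generalization: K-fold out-of-fold meta-features from M first-level
# pair learners, a small neural meta-learner trained by gradient descent, and
# the ensemble variants (full 4x4 grid, concatenated features, single
# technique).

#' Configuration of the stacking ensemble
#'
#' @param K Number of cross-validation folds (default 5).
#' @param learners List of learner configurations (default: the 4x4 grid of
#'   [default_learner_grid()], 16 learners = 4 encodings x 4 network
#'   configurations).
#' @param meta_layers Hidden-layer widths of the neural meta-learner.
#' @param eta Meta-learner gradient-descent learning rate.
#' @param max_iters Maximum meta-learner iterations (default 600).
#' @param epsilon Stopping threshold on the max-norm of the meta gradients.
#' @param seed Integer seed for fold assignment and meta initialization.
#' @return A list of class `ppi_stacking_config`.
#' @export
stacking_config <- function(K = 5, learners = default_learner_grid(),
                            meta_layers = c(32, 16), eta = 0.1,
                            max_iters = 600, epsilon = 1e-6, seed = 1) {
  assert_that(K >= 2, "`K` must be >= 2")
  assert_that(length(learners) >= 1, "need at least one learner")
  structure(list(K = as.integer(K), learners = learners,
                 meta_layers = as.integer(meta_layers), eta = eta,
                 max_iters = as.integer(max_iters), epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "ppi_stacking_config")
}

# the four first-level network configurations assigned to each encoding
.base_learner_variants <- function() {
  list(list(dense = c(128, 64), h = 2),
       list(dense = c(256, 128), h = 4),
       list(dense = c(128, 64, 32), h = 2),
       list(dense = c(256, 128, 64), h = 4))
}

#' The default 16-learner grid
#'
#' Four encodings (AC, CT, LD, PseAAC) each trained under four network
#' configurations (dense stacks 128-64, 256-128, 128-64-32, 256-128-64 with
#' 2 or 4 attention heads), giving the 16 first-level learners of the full
#' ensemble.
#'
#' @param techniques Encodings to include.
#' @param epochs,batch_size,lr,val_fraction,patience Training schedule shared
#'   by all learners.
#' @param seed Base seed; each learner derives its own stream from it.
#' @return A list of 16 [learner_config()] objects.
#' @export
default_learner_grid <- function(techniques = c("ac", "ct", "ld", "pseaac"),
                                 epochs = 8, batch_size = 32, lr = 3e-3,
                                 val_fraction = 0.15, patience = 4,
                                 seed = 1) {
  variants <- .base_learner_variants()
  grid <- list()
  for (tech in techniques) {
    for (v in seq_along(variants)) {
      nm <- sprintf("%s_cfg%d", tech, v)
      grid[[nm]] <- learner_config(
        technique = tech, h = variants[[v]]$h, dense = variants[[v]]$dense,
        epochs = epochs, batch_size = batch_size, lr = lr,
        val_fraction = val_fraction, patience = patience,
        seed = derive_seed(seed, nm), name = nm
      )
    }
  }
  grid
}

# seeded, label-stratified fold assignment
stratified_folds <- function(labels, K, seed) {
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      ids <- which(labels == cl)
      if (length(ids) < K) {
        stop("class ", cl, " has fewer members (", length(ids),
             ") than folds (", K, "); use fewer folds or another seed",
             call. = FALSE)
      }
      fold[ids] <- sample(rep_len(seq_len(K), length(ids)))
    }
  })
  fold
}

.features_for <- function(technique, features) {
  if (technique %in% names(features)) return(features[[technique]])
  if (technique == "concat") return(build_concat_features(features))
  stop("no feature set for technique '", technique, "'", call. = FALSE)
}

#' Build out-of-fold meta-features and fold models
#'
#' For each learner `m` and fold `k`, trains on the pairs outside fold `k`
#' and predicts the held-out fold, so row `i` of the returned meta matrix
#' contains, for each learner, a prediction made by a model whose training
#' data excluded pair `i` (the out-of-fold guarantee of stacking).
#'
#' @param pairs Labelled pair table (`idA`, `idB`, `label`).
#' @param features Named list of feature tibbles (by technique).
#' @param cfg A [stacking_config()].
#' @param verbose Print per-learner progress?
#' @return A list with `meta` (n x M matrix of positive-class
#'   probabilities), `fold_models` (M lists of K fitted learners), `fold_id`
#'   (fold assignment per pair) and `learner_names`.
#' @export
build_meta_features <- function(pairs, features, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "ppi_stacking_config"))
  y <- as.integer(pairs$label)
  fold_id <- stratified_folds(y, cfg$K, cfg$seed)
  M <- length(cfg$learners)
  n <- nrow(pairs)
  meta <- matrix(NA_real_, n, M)
  nms <- names(cfg$learners) %||%
    vapply(cfg$learners, function(l) l$name %||% "learner", character(1))
  colnames(meta) <- nms
  fold_models <- vector("list", M)
  names(fold_models) <- nms
  for (m in seq_len(M)) {
    lc <- cfg$learners[[m]]
    feats <- .features_for(lc$technique, features)
    fold_models[[m]] <- vector("list", cfg$K)
    for (k in seq_len(cfg$K)) {
      lc_k <- lc
      if (!is.null(lc_k$seed)) lc_k$seed <- derive_seed(lc$seed, paste0("fold", k))
      tr <- fold_id != k
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
        stop("fold ", k, " is single-class; re-stratify or change the seed",
             call. = FALSE)
      }
      model <- fit_learner(lc_k, pairs[tr, , drop = FALSE], feats)
      meta[!tr, m] <- predict_learner(model, pairs[!tr, , drop = FALSE], feats)
      fold_models[[m]][[k]] <- model
    }
    if (verbose) {
      message(sprintf("learner %s: out-of-fold AUC %.3f", nms[m],
                      auc_score(y, meta[, m])))
    }
  }
  list(meta = meta, fold_models = fold_models, fold_id = fold_id,
       learner_names = nms)
}

#' Meta-features for new pairs from the fold models
#'
#' Feature `(i, m)` is the mean over the K fold models of learner `m` of
#' their predicted positive-class probability for pair `i`
#' (`(T_1 + ... + T_K) / K`).
#'
#' @param pairs Pair table to score.
#' @param features Named list of feature tibbles.
#' @param fold_models The `fold_models` element of [build_meta_features()].
#' @param learner_configs The learner configurations (to resolve feature
#'   sets); defaults to reading the `config` of each first fold model.
#' @return An `nrow(pairs) x M` matrix.
#' @export
predict_meta_features <- function(pairs, features, fold_models,
                                  learner_configs = NULL) {
  M <- length(fold_models)
  out <- matrix(NA_real_, nrow(pairs), M)
  colnames(out) <- names(fold_models)
  for (m in seq_len(M)) {
    models <- fold_models[[m]]
    assert_that(length(models) >= 1 && !any(vapply(models, is.null, logical(1))),
                paste0("missing fold model(s) for learner ", m))
    tech <- if (!is.null(learner_configs)) {
      learner_configs[[m]]$technique
    } else {
      models[[1]]$config$technique %||% attr(models[[1]], "technique")
    }
    feats <- .features_for(tech, features)
    preds <- vapply(models, function(mod) predict_learner(mod, pairs, feats),
                    numeric(nrow(pairs)))
    out[, m] <- rowMeans(as.matrix(preds))
  }
  out
}

#' Train the neural meta-learner
#'
#' An L-layer network on the meta-feature matrix: ReLU hidden layers of
#' widths `cfg$meta_layers` and a 2-way softmax output, trained by
#' full-batch gradient descent at rate `eta` on the cross-entropy loss until
#' the max-norm of every gradient falls below `epsilon` or `max_iters`
#' iterations are reached. Deterministic given `cfg$seed`.
#'
#' @param meta Meta-feature matrix (n x M).
#' @param labels 0/1 labels of its rows.
#' @param cfg A [stacking_config()].
#' @return An object of class `ppi_meta`.
#' @export
train_meta <- function(meta, labels, cfg) {
  assert_that(nrow(meta) > 0, "empty meta-feature matrix")
  y <- as.integer(labels)
  widths <- c(ncol(meta), cfg$meta_layers, 2L)
  with_local_seed(derive_seed(cfg$seed, "meta"), {
    W <- list(); b <- list()
    for (l in seq_len(length(widths) - 1L)) {
      W[[l]] <- glorot_init(widths[l], widths[l + 1L])
      b[[l]] <- rep(0, widths[l + 1L])
    }
    L <- length(W)
    loss_hist <- numeric(0)
    iters <- 0L
    for (it in seq_len(cfg$max_iters)) {
      iters <- it
      acts <- list(meta)
      caches <- list()
      for (l in seq_len(L)) {
        z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
        a <- if (l < L) pmax(z, 0) else z
        caches[[l]] <- list(z = z)
        acts[[l + 1L]] <- a
      }
      sx <- softmax_xent(acts[[L + 1L]], y)
      if (!is.finite(sx$loss)) {
        stop("meta-learner loss became non-finite at iteration ", it,
             call. = FALSE)
      }
      loss_hist <- c(loss_hist, sx$loss)
      dh <- sx$dlogits
      gmax <- 0
      dW <- list(); db <- list()
      for (l in rev(seq_len(L))) {
        dW[[l]] <- crossprod(acts[[l]], dh)
        db[[l]] <- colSums(dh)
        gmax <- max(gmax, max(abs(dW[[l]])), max(abs(db[[l]])))
        if (l > 1L) dh <- (dh %*% t(W[[l]])) * (caches[[l - 1L]]$z > 0)
      }
      if (gmax < cfg$epsilon) break
      for (l in seq_len(L)) {
        W[[l]] <- W[[l]] - cfg$eta * dW[[l]]
        b[[l]] <- b[[l]] - cfg$eta * db[[l]]
      }
    }
    structure(list(W = W, b = b, loss = loss_hist, iters = iters,
                   feature_names = colnames(meta)),
              class = "ppi_meta")
  })
}

#' Positive-class probability from the meta-learner
#'
#' @param object A fitted `ppi_meta`.
#' @param meta Meta-feature matrix.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.ppi_meta <- function(object, meta, ...) {
  a <- as.matrix(meta)
  L <- length(object$W)
  for (l in seq_len(L)) {
    a <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    if (l < L) a <- pmax(a, 0)
  }
  row_softmax(a)[, 2]
}

#' Train a stacked ensemble of pair learners
#'
#' Full stacked generalization: builds K-fold out-of-fold meta-features from
#' the first-level learners ([build_meta_features()]) and trains the neural
#' meta-learner on them ([train_meta()]). `variant = "grid"` uses the
#' configured learner list (default 16 = 4 encodings x 4 configurations);
#' `"concat"` trains the four network configurations on the concatenated
#' AC+CT+LD+PseAAC representation; `"sep"` restricts the grid to a single
#' encoding given by `technique`.
#'
#' @param pairs Labelled pair table.
#' @param features Named list of feature tibbles (one per technique).
#' @param cfg A [stacking_config()].
#' @param variant `"grid"`, `"concat"` or `"sep"`.
#' @param technique Encoding for `variant = "sep"`.
#' @param verbose Print progress?
#' @return An object of class `ppi_ensemble`.
#' @export
train_ensemble <- function(pairs, features, cfg = stacking_config(),
                           variant = c("grid", "concat", "sep"),
                           technique = NULL, verbose = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(cfg, "ppi_stacking_config"))
  if (variant != "grid") {
    proto <- cfg$learners[[1]]
    techs <- if (variant == "concat") "concat" else {
      assert_that(!is.null(technique),
                  "`technique` is required for variant = \"sep\"")
      technique
    }
    cfg$learners <- default_learner_grid(
      techniques = techs, epochs = proto$epochs,
      batch_size = proto$batch_size, lr = proto$lr,
      val_fraction = proto$val_fraction, patience = proto$patience,
      seed = cfg$seed
    )
  }
  mf <- build_meta_features(pairs, features, cfg, verbose = verbose)
  meta_model <- train_meta(mf$meta, pairs$label, cfg)
  y <- as.integer(pairs$label)
  oof_auc <- apply(mf$meta, 2, function(p) auc_score(y, p))
  structure(list(config = cfg, variant = variant,
                 fold_models = mf$fold_models, fold_id = mf$fold_id,
                 meta = mf$meta, meta_model = meta_model,
                 meta_feature_names = mf$learner_names,
                 labels = y, oof_auc = oof_auc),
            class = "ppi_ensemble")
}

#' Predict interactions with a stacked ensemble
#'
#' @param object A fitted `ppi_ensemble`.
#' @param pairs Pair table with columns `idA`, `idB`.
#' @param features Named list of feature tibbles.
#' @param threshold Decision threshold for `.pred_class` (default 0.5).
#' @param ... Unused.
#' @return A tibble with `idA`, `idB`, `.pred` (positive probability) and
#'   `.pred_class`.
#' @export
predict.ppi_ensemble <- function(object, pairs, features, threshold = 0.5,
                                 ...) {
  tm <- predict_meta_features(pairs, features, object$fold_models,
                              object$config$learners)
  p <- predict(object$meta_model, tm)
  tibble::tibble(idA = pairs$idA, idB = pairs$idB, .pred = p,
                 .pred_class = as.integer(p >= threshold))
}

#' @export
print.ppi_ensemble <- function(x, ...) {
  cat("<ppi_ensemble>", x$variant, "variant:",
      length(x$fold_models), "learners x", x$config$K, "folds on",
      length(x$labels), "pairs\n")
  cat("  out-of-fold AUC:",
      sprintf("best %.3f / median %.3f", max(x$oof_auc),
              stats::median(x$oof_auc)), "\n")
  cat("  meta-learner:", paste(x$config$meta_layers, collapse = "-"),
      "hidden units,", x$meta_model$iters, "iterations\n")
  invisible(x)
}
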