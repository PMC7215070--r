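# Stub first-level learners for exercising the stacking machinery without
# network training. Each stub records the unordered-pair keys it was trained
# on (for leakage audits) and predicts a configurable function of the pair.

stub_learner_config <- function(predictor = NULL, name = "stub") {
  structure(list(predictor = predictor, name = name, technique = "ct"),
            class = "stub_learner_config")
}

fit_learner.stub_learner_config <- function(cfg, pairs, features) {
  structure(list(
    config = cfg,
    train_keys = paste(pairs$idA, pairs$idB, sep = "/"),
    train_rate = mean(pairs$label)
  ), class = "stub_learner")
}

predict_learner.stub_learner <- function(model, pairs, features) {
  if (is.null(model$config$predictor)) {
    rep(model$train_rate, nrow(pairs))          # majority-rate stub
  } else {
    model$config$predictor(model, pairs)
  }
}

register_stub_methods <- function() {
  registerS3method("fit_learner", "stub_learner_config",
                   fit_learner.stub_learner_config,
                   envir = asNamespace("stackppi"))
  registerS3method("predict_learner", "stub_learner",
                   predict_learner.stub_learner,
                   envir = asNamespace("stackppi"))
}
register_stub_methods()

# small deterministic pair dataset over `n` proteins with features
make_toy_pairs <- function(n_proteins = 12, n_pairs = 24, seed = 1,
                           feature_dim = 14) {
  withr::with_seed(seed, {
    ids <- sprintf("T%02d", seq_len(n_proteins))
    all_pairs <- t(utils::combn(ids, 2))
    take <- sample(nrow(all_pairs), n_pairs)
    pairs <- pair_dataset(tibble::tibble(
      idA = all_pairs[take, 1], idB = all_pairs[take, 2],
      label = sample(0:1, n_pairs, replace = TRUE)
    ))
    mat <- matrix(rnorm(n_proteins * feature_dim), n_proteins)
    feats <- dplyr::bind_cols(tibble::tibble(id = ids),
                              tibble::as_tibble(mat, .name_repair = "minimal"))
    names(feats) <- c("id", paste0("f", seq_len(feature_dim)))
    list(pairs = pairs, features = feats)
  })
}

# a linearly separable pair-classification task: proteins belong to a "+" or
# "-" pool with well separated feature means; a pair is positive iff both
# proteins come from the "+" pool
make_trivial_task <- function(n_proteins = 40, n_pairs = 240, seed = 3,
                              feature_dim = 14, shift = 3) {
  withr::with_seed(seed, {
    ids <- sprintf("S%02d", seq_len(n_proteins))
    cls <- rep(c(1, 0), length.out = n_proteins)
    mat <- matrix(rnorm(n_proteins * feature_dim), n_proteins) +
      shift * cls
    feats <- dplyr::bind_cols(tibble::tibble(id = ids),
                              tibble::as_tibble(mat, .name_repair = "minimal"))
    names(feats) <- c("id", paste0("f", seq_len(feature_dim)))
    all_pairs <- t(utils::combn(seq_len(n_proteins), 2))
    take <- sample(nrow(all_pairs), n_pairs)
    pairs <- pair_dataset(tibble::tibble(
      idA = ids[all_pairs[take, 1]],
      idB = ids[all_pairs[take, 2]],
      label = as.integer(cls[all_pairs[take, 1]] == 1 &
                           cls[all_pairs[take, 2]] == 1)
    ))
    list(pairs = pairs, features = feats)
  })
}

# deterministic stub grid whose predictions vary by pair (for audits)
stub_grid_accept <- function(M) {
  g <- lapply(seq_len(M), function(m) {
    stub_learner_config(predictor = function(model, pairs) {
      key <- paste(pairs$idA, pairs$idB, sep = "/")
      h <- vapply(key, function(k) sum(utf8ToInt(k)), numeric(1))
      unname((h %% 97) / 96)
    }, name = paste0("astub", m))
  })
  names(g) <- paste0("astub", seq_len(M))
  g
}
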