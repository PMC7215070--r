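# Stacked generalization: out-of-fold bookkeeping, test-time averaging, the
# neural meta-learner, and the ensemble variants. Network-free stub learners
# (helper-stubs.R) isolate the stacking machinery from training noise.

stub_grid <- function(M, predictor = NULL) {
  g <- lapply(seq_len(M), function(m) {
    stub_learner_config(predictor = predictor, name = paste0("stub", m))
  })
  names(g) <- paste0("stub", seq_len(M))
  g
}

test_that("meta-feature construction has the right shape and fold audit", {
  toy <- make_toy_pairs(n_proteins = 16, n_pairs = 40, seed = 2)
  cfg <- stacking_config(K = 4, learners = stub_grid(3), seed = 5)
  mf <- build_meta_features(toy$pairs, list(ct = toy$features), cfg)
  expect_equal(dim(mf$meta), c(40, 3))
  expect_false(anyNA(mf$meta))
  # out-of-fold guarantee: the model that produced feature (i, m) was
  # trained without pair i
  keys <- paste(toy$pairs$idA, toy$pairs$idB, sep = "/")
  for (m in seq_along(mf$fold_models)) {
    for (i in seq_len(nrow(toy$pairs))) {
      k <- mf$fold_id[i]
      expect_false(keys[i] %in% mf$fold_models[[m]][[k]]$train_keys)
    }
  }
  # stratified folds: both classes in every fold
  for (k in seq_len(cfg$K)) {
    expect_setequal(unique(toy$pairs$label[mf$fold_id == k]), c(0L, 1L))
  }
})

test_that("majority-rate stub reproduces the hand-computable meta feature", {
  # 6 pairs, labels 1,1,1,0,0,0; M = 1, K = 2: the held-out half's feature
  # is the training half's positive rate
  ids <- sprintf("M%02d", 1:12)
  pairs <- pair_dataset(tibble::tibble(
    idA = ids[1:6], idB = ids[7:12], label = c(1L, 1L, 1L, 0L, 0L, 0L)))
  feats <- tibble::tibble(id = ids, f1 = 0, f2 = 0)
  cfg <- stacking_config(K = 2, learners = stub_grid(1), seed = 9)
  mf <- build_meta_features(pairs, list(ct = feats), cfg)
  for (i in 1:6) {
    expect_equal(unname(mf$meta[i, 1]),
                 mean(pairs$label[mf$fold_id != mf$fold_id[i]]))
  }
})

test_that("test meta-features are the K-fold mean of fold-model predictions", {
  toy <- make_toy_pairs(seed = 4)
  # two stub fold models predicting 0.2 and 0.6 -> averaged feature 0.4
  mk <- function(p) structure(list(config = stub_learner_config(
    predictor = function(model, pairs) rep(p, nrow(pairs)))),
    class = "stub_learner")
  fm <- list(stubA = list(mk(0.2), mk(0.6)))
  tm <- predict_meta_features(toy$pairs, list(ct = toy$features), fm,
                              list(stub_learner_config()))
  expect_equal(unname(tm[, 1]), rep(0.4, nrow(toy$pairs)))
  # identical fold models: the average equals any single model
  fm2 <- list(stubA = list(mk(0.3), mk(0.3), mk(0.3)))
  tm2 <- predict_meta_features(toy$pairs, list(ct = toy$features), fm2,
                               list(stub_learner_config()))
  expect_equal(unname(tm2[, 1]), rep(0.3, nrow(toy$pairs)))
  expect_true(all(tm >= 0 & tm <= 1))
})

test_that("the meta-learner fits separable features and is deterministic", {
  withr::with_seed(11, {
    n <- 120
    y <- rep(c(0L, 1L), n / 2)
    meta <- cbind(a = y + rnorm(n, sd = 0.05),
                  b = 1 - y + rnorm(n, sd = 0.05))
    cfg <- stacking_config(K = 2, learners = stub_grid(2),
                           meta_layers = c(8), eta = 0.5, max_iters = 400,
                           seed = 3)
    mm <- train_meta(meta, y, cfg)
    acc <- mean((predict(mm, meta) >= 0.5) == (y == 1))
    expect_gte(acc, 0.99)
    mm2 <- train_meta(meta, y, cfg)
    expect_identical(mm$W, mm2$W)
    # single linear layer on a convex problem: loss is non-increasing
    cfg0 <- stacking_config(K = 2, learners = stub_grid(2),
                            meta_layers = integer(0), eta = 0.1,
                            max_iters = 200, seed = 3)
    mm0 <- train_meta(meta, y, cfg0)
    expect_true(all(diff(mm0$loss) <= 1e-8))
  })
})

test_that("an oracle first-level learner yields a perfect ensemble", {
  toy <- make_toy_pairs(n_proteins = 20, n_pairs = 60, seed = 6)
  lab <- stats::setNames(toy$pairs$label,
                         paste(toy$pairs$idA, toy$pairs$idB, sep = "/"))
  oracle_pred <- function(model, pairs) {
    unname(lab[paste(pairs$idA, pairs$idB, sep = "/")])
  }
  cfg <- stacking_config(K = 3, learners = stub_grid(2, oracle_pred),
                         meta_layers = c(4), eta = 0.5, max_iters = 500,
                         seed = 7)
  ens <- train_ensemble(toy$pairs, list(ct = toy$features), cfg)
  pr <- predict(ens, toy$pairs, list(ct = toy$features))
  expect_equal(mean(pr$.pred_class == toy$pairs$label), 1)
  expect_true(all(pr$.pred >= 0 & pr$.pred <= 1))
})

test_that("reordering learners permutes meta-feature columns", {
  toy <- make_toy_pairs(seed = 8)
  p1 <- function(model, pairs) rep(0.2, nrow(pairs))
  p2 <- function(model, pairs) rep(0.7, nrow(pairs))
  g <- list(a = stub_learner_config(p1, "a"), b = stub_learner_config(p2, "b"))
  cfg_ab <- stacking_config(K = 2, learners = g, seed = 5)
  cfg_ba <- stacking_config(K = 2, learners = rev(g), seed = 5)
  mf_ab <- build_meta_features(toy$pairs, list(ct = toy$features), cfg_ab)
  mf_ba <- build_meta_features(toy$pairs, list(ct = toy$features), cfg_ba)
  expect_equal(mf_ab$meta[, c("a", "b")], mf_ba$meta[, c("a", "b")])
})

test_that("ensemble variants select the expected inputs", {
  recs <- withr::with_seed(3, tibble::tibble(
    id = sprintf("V%02d", 1:10),
    seq = replicate(10, random_aa_seq(70))))
  fl <- encode_feature_sets(recs, lambda = 15)
  cc <- build_concat_features(fl)
  expect_equal(ncol(cc) - 1, 210 + 343 + 630 + 35)
  # "sep" restricts every learner to one technique
  proto <- default_learner_grid(epochs = 1, seed = 2)
  cfg <- stacking_config(K = 2, learners = proto, seed = 2)
  expect_error(train_ensemble(tibble::tibble(), fl, cfg, variant = "sep"),
               "technique")
  grid_ac <- default_learner_grid("ac", epochs = 1, seed = 2)
  expect_true(all(vapply(grid_ac, function(l) l$technique, "") == "ac"))
  expect_length(default_learner_grid(), 16)
  # concat learners reshape the padded concatenated vector 7 channels wide
  dims <- stackppi:::reshape_dims("concat", ncol(cc) - 1)
  expect_equal(unname(dims["P"] * dims["Cin"] >= ncol(cc) - 1), TRUE)
})

test_that("single-class folds are rejected with advice", {
  ids <- sprintf("S%02d", 1:8)
  pairs <- pair_dataset(tibble::tibble(idA = ids[1:4], idB = ids[5:8],
                                       label = c(1L, 1L, 1L, 0L)))
  feats <- tibble::tibble(id = ids, f1 = 0)
  cfg <- stacking_config(K = 3, learners = stub_grid(1), seed = 1)
  expect_error(build_meta_features(pairs, list(ct = feats), cfg), "folds")
})

test_that("tidy and glance summarise a fitted ensemble", {
  toy <- make_toy_pairs(seed = 10)
  rate_pred <- function(model, pairs) {
    r <- rep(model$train_rate, nrow(pairs))
    r + seq_len(nrow(pairs)) * 1e-3   # break ties for the AUC
  }
  cfg <- stacking_config(K = 2, learners = stub_grid(2, rate_pred),
                         meta_layers = c(4), max_iters = 50, seed = 2)
  # a grid of real learner configs is needed for tidy()'s metadata
  cfg$learners <- lapply(cfg$learners, function(l) {
    lc <- learner_config("ct", epochs = 1, seed = 1, name = l$name)
    class(lc) <- "stub_learner_config"
    lc$predictor <- rate_pred
    lc
  })
  ens <- train_ensemble(toy$pairs, list(ct = toy$features), cfg)
  td <- tidy(ens)
  expect_equal(nrow(td), 2)
  expect_named(td, c("learner", "technique", "heads", "dense", "oof_auc"))
  gl <- glance(ens)
  expect_equal(gl$n_learners, 2)
  expect_equal(gl$folds, 2)
  p <- ggplot2::autoplot(ens)
  expect_s3_class(p, "ggplot")
})

test_that("all ensemble variants train on a small synthetic set", {
  cfg <- sim_config(n_proteins = 90, n_positive_pairs = 40,
                    length_range = c(60, 120), seed = 17)
  ds <- simulate_ppi_dataset(cfg)
  fl <- encode_feature_sets(ds$records, lambda = 8)
  base <- stacking_config(
    K = 3,
    learners = default_learner_grid(epochs = 1, seed = 3),
    meta_layers = c(4), max_iters = 30, seed = 3
  )
  # one cheap learner per technique for the grid variant
  base$learners <- lapply(base$learners[c("ac_cfg1", "pseaac_cfg1")],
                          function(l) { l$epochs <- 1L; l })
  for (v in c("grid", "concat", "sep")) {
    ens <- train_ensemble(ds$pairs, fl, base, variant = v,
                          technique = if (v == "sep") "pseaac")
    pr <- predict(ens, ds$pairs[1:10, ], fl)
    expect_true(all(pr$.pred >= 0 & pr$.pred <= 1))
    expect_equal(nrow(pr), 10)
    if (v == "sep") {
      techs <- vapply(ens$config$learners, function(l) l$technique, "")
      expect_true(all(techs == "pseaac"))
    }
    if (v == "concat") {
      expect_equal(ens$fold_models[[1]][[1]]$n_features, 210 + 343 + 630 + 28)
    }
  }
})
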