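# The pair classifier: attention and merge operations against brute-force
# oracles, gradient correctness, and training contracts.

test_that("scaled dot-product attention is row-stochastic and exact", {
  withr::with_seed(3, {
    Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(10), 5, 2)
    V <- matrix(rnorm(15), 5, 3)
    at <- scaled_dot_attention(Q, K, V)
    expect_equal(rowSums(at$weights), rep(1, 4), tolerance = 1e-12)
    o <- oracle_attention(Q, K, V)
    expect_equal(at$weights, o$weights, tolerance = 1e-12)
    expect_equal(at$output, o$output, tolerance = 1e-12)
  })
  # 2x2 numeric case: Q = K = I, V given; weights from softmax(I/sqrt(2))
  at <- scaled_dot_attention(diag(2), diag(2), matrix(c(1, 3, 2, 4), 2))
  w <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + exp(0))
  expect_equal(at$weights, matrix(c(w, 1 - w, 1 - w, w), 2), tolerance = 1e-12)
  expect_equal(at$output[1, 1], w * 1 + (1 - w) * 3, tolerance = 1e-12)
  # saturation: a query aligned with one large-norm orthogonal key
  K2 <- diag(2) * 50
  at2 <- scaled_dot_attention(matrix(c(1, 0), 1), K2, matrix(c(1, 2, 3, 4), 2))
  expect_gt(at2$weights[1, 1], 0.999999)
  expect_equal(at2$output[1, ], c(1, 3), tolerance = 1e-4)
  expect_error(scaled_dot_attention(matrix(0, 2, 3), matrix(0, 2, 2),
                                    matrix(0, 2, 2)), "key width")
})

test_that("multi-head attention reduces, preserves shape and ignores K/V order", {
  withr::with_seed(4, {
    Q <- matrix(rnorm(12), 4, 3); K <- matrix(rnorm(18), 6, 3)
    V <- matrix(rnorm(18), 6, 3)
    # h = 1 with identity projections reduces to single-head attention
    w1 <- list(Wq = list(diag(3)), Wk = list(diag(3)), Wv = list(diag(3)),
               Wo = diag(3))
    expect_equal(multi_head(Q, K, V, w1),
                 scaled_dot_attention(Q, K, V)$output, tolerance = 1e-12)
    w <- random_mh_weights(3, h = 2, dk = 2, d_model = 3)
    M <- multi_head(Q, K, V, w)
    expect_equal(nrow(M), nrow(Q))
    expect_equal(M, oracle_multi_head(Q, K, V, w), tolerance = 1e-12)
    # jointly permuting key/value rows leaves the output unchanged
    perm <- sample(6)
    expect_equal(multi_head(Q, K[perm, ], V[perm, ], w), M, tolerance = 1e-12)
  })
})

test_that("pooled attention yields fixed-length output independent of keys", {
  withr::with_seed(5, {
    Q <- matrix(rnorm(12), 4, 3)
    w <- random_mh_weights(3, h = 1, dk = 3, d_model = 3)
    for (nk in c(3, 7)) {
      K <- matrix(rnorm(nk * 3), nk, 3); V <- matrix(rnorm(nk * 3), nk, 3)
      pv <- pooled_multi_head(Q, K, V, w)
      expect_length(pv, 2 * nrow(Q))
      expect_equal(pv, oracle_pooled_multi_head(Q, K, V, w),
                   tolerance = 1e-12)
    }
  })
  # constant interaction map: average and max pooling halves coincide
  wI <- list(Wq = list(diag(2) * 0), Wk = list(diag(2) * 0),
             Wv = list(diag(2) * 0), Wo = diag(2))
  Qc <- matrix(1, 3, 2)
  pv <- pooled_multi_head(Qc, Qc, Qc, wI)
  expect_equal(pv[1:3], pv[4:6], tolerance = 1e-12)
})

test_that("the merge layer concatenates similarity, bilinear and both vectors", {
  s <- c(1, 2, 2)
  m <- merge_pair(s, s, diag(3))
  expect_equal(unname(m[1]), 1)                  # cosine of a vector with itself
  expect_equal(unname(m[2]), sum(s^2))           # bilinear with identity
  expect_length(m, 2 * 3 + 2)
  o <- merge_pair(c(1, 0), c(0, 1), diag(2))
  expect_equal(unname(o[1:2]), c(0, 0))
  z <- merge_pair(c(0, 0), c(1, 1), diag(2))
  expect_equal(unname(z[1]), 0)                  # zero-norm cosine is 0, not NaN
  withr::with_seed(6, {
    for (i in 1:5) {
      d <- sample(2:6, 1)
      s1 <- rnorm(d); s2 <- rnorm(d); A <- matrix(rnorm(d * d), d)
      expect_equal(unname(merge_pair(s1, s2, A)), oracle_merge(s1, s2, A),
                   tolerance = 1e-12)
    }
  })
})

test_that("the convolution stack honours its shape and linearity contracts", {
  withr::with_seed(7, {
    P <- 6; Cin <- 2; C <- 3; k <- 3
    wts <- list(blocks = list(list(W = matrix(rnorm(k * Cin * C), k * Cin),
                                   b = rep(0, C), gamma = rep(1, C),
                                   beta = rep(0, C))),
                final = list(W = matrix(rnorm(k * C * C), k * C),
                             b = rep(0, C)))
    x <- matrix(rnorm(P * Cin), P)
    out <- conv_stack(x, wts, kernel = k)
    expect_equal(dim(out), c(P, C))            # 'same' padding keeps positions
    # zero input stays zero through zero-bias convolutions (pre-BN shift)
    x0 <- matrix(0, P, Cin)
    cv <- stackppi:::conv_fwd(x0, wts$blocks[[1]]$W, wts$blocks[[1]]$b,
                              stackppi:::conv_gather_index(1L, P, 3L), 3L)
    expect_equal(max(abs(cv$out)), 0)
    expect_error(conv_stack(matrix(0, 4, 5), wts, kernel = k), "expected")
  })
  # hand-computed convolution on a 6-position single-channel input
  x <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1)
  W <- matrix(c(1, 0, -1), 3, 1)   # taps: previous, current, next position
  idx <- stackppi:::conv_gather_index(1L, 6L, 3L)
  out <- stackppi:::conv_fwd(x, W, 0, idx, 3L)$out
  # position i: 1*x[i-1] + 0*x[i] - 1*x[i+1] (zeros beyond the ends)
  expect_equal(as.numeric(out), c(-2, -2, -2, -2, -2, 5))
})

test_that("the batched training path reproduces the single-sample operations", {
  withr::with_seed(8, {
    cfg <- learner_config("ct", h = 2, dense = c(8), channels = 4, seed = 3)
    P <- 5L; Cin <- 2L; B <- 4L
    params <- init_learner_weights(cfg, P, Cin)
    X1 <- matrix(rnorm(B * P * Cin), B); X2 <- matrix(rnorm(B * P * Cin), B)
    rs <- list(mean = list(rep(0, 4)), var = list(rep(1, 4)))
    fw <- stackppi:::.learner_fwd(params, X1, X2, cfg, P, Cin, FALSE, rs)
    wts <- list(blocks = list(list(W = params$convW1, b = params$convb1,
                                   gamma = params$gamma1, beta = params$beta1)),
                final = list(W = params$fconvW, b = params$fconvb))
    mh <- list(Wq = list(params$Wq[, 1:2], params$Wq[, 3:4]),
               Wk = list(params$Wk[, 1:2], params$Wk[, 3:4]),
               Wv = list(params$Wv[, 1:2], params$Wv[, 3:4]),
               Wo = params$Wo)
    bn_stats <- list(list(mean = rs$mean[[1]], var = rs$var[[1]]))
    for (b in seq_len(B)) {
      x1 <- matrix(X1[b, ], P, Cin, byrow = TRUE)
      x2 <- matrix(X2[b, ], P, Cin, byrow = TRUE)
      H1 <- conv_stack(x1, wts, kernel = 3, bn_stats = bn_stats)
      H2 <- conv_stack(x2, wts, kernel = 3, bn_stats = bn_stats)
      S1p <- pooled_multi_head(H1, H2, H1, mh)
      S2p <- pooled_multi_head(H2, H1, H2, mh)
      expect_equal(max(abs(H1 - fw$H1[(b - 1) * P + 1:P, ])), 0,
                   tolerance = 1e-12)
      expect_equal(unname(S1p), unname(fw$S1p[b, ]), tolerance = 1e-12)
      expect_equal(unname(merge_pair(S1p, S2p, params$Abil)),
                   unname(fw$Z[b, ]), tolerance = 1e-12)
    }
  })
})

test_that("hand-derived gradients match finite differences", {
  withr::with_seed(42, {
    cfg <- learner_config("ct", h = 2, dense = c(5), channels = 4, seed = 7)
    P <- 6L; Cin <- 2L; B <- 3L
    params <- init_learner_weights(cfg, P, Cin)
    X1 <- matrix(rnorm(B * P * Cin), B); X2 <- matrix(rnorm(B * P * Cin), B)
    y <- c(0L, 1L, 1L)
    rs <- list(mean = list(rep(0, 4)), var = list(rep(1, 4)))
    lossfun <- function(p) {
      fw <- stackppi:::.learner_fwd(p, X1, X2, cfg, P, Cin, TRUE, rs)
      stackppi:::softmax_xent(fw$logits, y)$loss
    }
    fw <- stackppi:::.learner_fwd(params, X1, X2, cfg, P, Cin, TRUE, rs)
    sx <- stackppi:::softmax_xent(fw$logits, y)
    gr <- stackppi:::.learner_bwd(sx$dlogits, fw, params, cfg, P, Cin)
    eps <- 1e-6
    for (nm in names(gr)) {
      p0 <- params[[nm]]
      for (i in sample(length(p0), min(4, length(p0)))) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
        # absolute + relative: biases feeding straight into batch norm have
        # exactly zero effect, where relative error is meaningless
        expect_lt(abs(num - gr[[nm]][i]),
                  1e-5 + 1e-4 * (abs(num) + abs(gr[[nm]][i])))
      }
    }
  })
})

test_that("training is deterministic, probabilistic and class-checked", {
  toy <- make_trivial_task()
  cfg <- learner_config("ct", h = 2, dense = c(16), channels = 4,
                        epochs = 4, batch_size = 16, val_fraction = 0,
                        seed = 5)
  m1 <- train_basic(toy$pairs, toy$features, cfg)
  m2 <- train_basic(toy$pairs, toy$features, cfg)
  expect_identical(m1$params, m2$params)
  pr <- predict(m1, toy$pairs, toy$features)
  expect_equal(pr$.pred_0 + pr$.pred_1, rep(1, nrow(pr)), tolerance = 1e-12)
  expect_true(all(pr$.pred_1 >= 0 & pr$.pred_1 <= 1))
  mono <- toy$pairs
  mono$label <- 1L
  expect_error(train_basic(mono, toy$features, cfg), "both classes")
})

test_that("a linearly trivial planted task is learned almost perfectly", {
  toy <- make_trivial_task(n_proteins = 40, n_pairs = 300, seed = 12)
  split <- withr::with_seed(2, sample(nrow(toy$pairs)))
  tr <- toy$pairs[split[1:240], ]
  te <- toy$pairs[split[241:300], ]
  cfg <- learner_config("ct", h = 2, dense = c(32, 16), channels = 4,
                        epochs = 25, batch_size = 32, lr = 3e-3,
                        val_fraction = 0.15, patience = 8, seed = 31)
  m <- train_basic(tr, toy$features, cfg)
  pr <- predict(m, te, toy$features)
  acc <- mean((pr$.pred_1 >= 0.5) == (te$label == 1))
  expect_gt(acc, 0.9)
})
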