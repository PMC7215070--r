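# The basic pair learner: a siamese convolution stack over both encoded
# proteins, multi-head cross-attention with average/max pooling in both
# directions, a merge layer (cosine + bilinear + both representations) and a
# dense softmax classifier, trained end-to-end by cross-entropy with Adam.
# The forward/backward passes here are batched versions of the single-sample
# operations in attention-ops.R; equivalence and gradient correctness are
# asserted in the test suite.

#' Configuration of one basic pair learner
#'
#' @param technique Encoding the learner consumes: `"ac"`, `"ct"`, `"ld"`,
#'   `"pseaac"` or `"concat"`.
#' @param h Number of attention heads (must divide `channels`).
#' @param dense Integer vector of hidden dense-layer widths.
#' @param n_blocks Number of convolution + batch-norm + ReLU blocks before
#'   the closing convolution.
#' @param channels Convolution output channels; also the attention model
#'   width `d_model` (so `d_k = channels / h`).
#' @param kernel Convolution width (odd).
#' @param epochs,batch_size,lr Training schedule (Adam learning rate `lr`).
#' @param val_fraction Fraction of the training pairs held out for early
#'   stopping (0 disables early stopping).
#' @param patience Early-stopping patience in epochs.
#' @param symmetrize Train on both orientations of every (unordered) pair
#'   and average the two orientations at prediction time, enforcing the
#'   symmetry of the interaction relation (default `TRUE`).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param name Optional label used in meta-feature column names.
#' @return A list of class `ppi_learner_config`.
#' @export
learner_config <- function(technique, h = 2, dense = c(128, 64),
                           n_blocks = 1, channels = 8, kernel = 3,
                           epochs = 30, batch_size = 32, lr = 1e-3,
                           val_fraction = 0.15, patience = 5,
                           symmetrize = TRUE,
                           seed = 1, name = NULL) {
  assert_that(channels %% h == 0, "`channels` must be divisible by `h`")
  assert_that(kernel %% 2 == 1, "`kernel` must be odd")
  assert_that(n_blocks >= 1, "`n_blocks` must be >= 1")
  structure(list(
    technique = technique, h = as.integer(h), dense = as.integer(dense),
    n_blocks = as.integer(n_blocks), channels = as.integer(channels),
    kernel = as.integer(kernel), epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), lr = lr,
    val_fraction = val_fraction, patience = as.integer(patience),
    symmetrize = isTRUE(symmetrize),
    seed = as.integer(seed),
    name = name %||% sprintf("%s_h%d_d%s", technique, h,
                             paste(dense, collapse = "-"))
  ), class = "ppi_learner_config")
}

# (positions, channels) interpretation of a flat encoded vector: the three
# group/property encodings carry 7 values per position, PseAAC is a single
# profile, and the concatenated representation is zero-padded to a multiple
# of 7 and read 7 channels wide.
reshape_dims <- function(technique, d) {
  if (technique == "pseaac") return(c(P = d, Cin = 1L))
  if (technique == "concat") return(c(P = as.integer(ceiling(d / 7)), Cin = 7L))
  assert_that(d %% 7 == 0, paste0("feature length ", d,
                                  " is not a multiple of 7"))
  c(P = as.integer(d / 7), Cin = 7L)
}

# flat (B, P*Cin) batch -> stacked (B*P, Cin) row-major sequence form
to_seq_form <- function(X, P, Cin) {
  t(matrix(t(X), nrow = Cin))
}

from_seq_form <- function(Xs, P, Cin) {
  t(matrix(t(Xs), nrow = P * Cin))
}

#' Initialize the weights of a basic learner
#'
#' Glorot-uniform initialization of every trainable tensor for a learner
#' whose reshaped input has `P` positions and `Cin` channels. Uses the
#' current RNG stream.
#'
#' @param cfg A [learner_config()].
#' @param P,Cin Input positions and channels.
#' @return A named list of parameter matrices/vectors.
#' @export
init_learner_weights <- function(cfg, P, Cin) {
  C <- cfg$channels; k <- cfg$kernel
  params <- list()
  cin <- Cin
  for (i in seq_len(cfg$n_blocks)) {
    params[[paste0("convW", i)]] <- glorot_init(k * cin, C)
    params[[paste0("convb", i)]] <- rep(0, C)
    params[[paste0("gamma", i)]] <- rep(1, C)
    params[[paste0("beta", i)]] <- rep(0, C)
    cin <- C
  }
  params$fconvW <- glorot_init(k * C, C)
  params$fconvb <- rep(0, C)
  params$Wq <- glorot_init(C, C)
  params$Wk <- glorot_init(C, C)
  params$Wv <- glorot_init(C, C)
  params$Wo <- glorot_init(C, C)
  params$Abil <- glorot_init(2L * P, 2L * P)
  din <- 4L * P + 2L
  # merge features mix a bounded cosine, an unbounded bilinear form and two
  # pooled maps of very different scales; normalizing them conditions the
  # dense head
  params$mgamma <- rep(1, din)
  params$mbeta <- rep(0, din)
  for (j in seq_along(cfg$dense)) {
    params[[paste0("dW", j)]] <- glorot_init(din, cfg$dense[j])
    params[[paste0("db", j)]] <- rep(0, cfg$dense[j])
    din <- cfg$dense[j]
  }
  params$dWout <- glorot_init(din, 2L)
  params$dbout <- rep(0, 2L)
  params
}

# ---- forward ---------------------------------------------------------------

# conv stack over the stacked pair batch (2B blocks of P rows)
.conv_stack_fwd <- function(Xs, params, cfg, nb, P, train, run_stats,
                            conv_idx = NULL) {
  k <- cfg$kernel
  idx <- conv_idx %||% conv_gather_index(nb, P, k)
  caches <- list()
  h <- Xs
  for (i in seq_len(cfg$n_blocks)) {
    cv <- conv_fwd(h, params[[paste0("convW", i)]],
                   params[[paste0("convb", i)]], idx, k)
    if (train) {
      bn <- bn_fwd(cv$out, params[[paste0("gamma", i)]],
                   params[[paste0("beta", i)]])
      run_stats$mean[[i]] <- 0.9 * run_stats$mean[[i]] + 0.1 * bn$mu
      run_stats$var[[i]] <- 0.9 * run_stats$var[[i]] + 0.1 * bn$var
    } else {
      bn <- list(out = bn_fwd_infer(cv$out, params[[paste0("gamma", i)]],
                                    params[[paste0("beta", i)]],
                                    run_stats$mean[[i]], run_stats$var[[i]]))
    }
    rl <- relu_fwd(bn$out)
    caches[[i]] <- list(conv = cv, bn = bn, relu = rl, cin = ncol(h))
    h <- rl$out
  }
  fc <- conv_fwd(h, params$fconvW, params$fconvb, idx, k)
  list(out = fc$out, fconv = fc, caches = caches, idx = idx,
       run_stats = run_stats)
}

# one cross-attention direction (query/value side Hq, key side Hk) with
# pooling; B row-blocks of P rows each
.attn_dir_fwd <- function(Hq, Hk, params, cfg, B, P) {
  C <- cfg$channels; hN <- cfg$h; dk <- C %/% hN
  Qp <- Hq %*% params$Wq
  Kp <- Hk %*% params$Wk
  Vp <- Hq %*% params$Wv
  heads <- vector("list", hN)
  Amats <- vector("list", hN)
  for (i in seq_len(hN)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    hd <- attn_head_cpp(Qp[, cols, drop = FALSE], Kp[, cols, drop = FALSE],
                        Vp[, cols, drop = FALSE], B)
    heads[[i]] <- hd$head
    Amats[[i]] <- hd$A
  }
  concat <- do.call(cbind, heads)
  M <- concat %*% params$Wo
  pm <- pool_map_cpp(M, Hq, B)                  # G = M Hq', pooled both ways
  pooled <- cbind(t(matrix(pm$avg, P, B)), t(matrix(pm$mx, P, B)))  # (B, 2P)
  list(pooled = pooled, Qp = Qp, Kp = Kp, Vp = Vp, A = Amats,
       concat = concat, M = M, amax = pm$amax)
}

.attn_dir_bwd <- function(dpooled, cache, Hq, Hk, params, cfg, B, P) {
  C <- cfg$channels; hN <- cfg$h; dk <- C %/% hN
  davg <- as.vector(t(dpooled[, seq_len(P), drop = FALSE]))
  dmx <- as.vector(t(dpooled[, P + seq_len(P), drop = FALSE]))
  pb <- pool_map_bwd_cpp(cache$M, Hq, davg, dmx, cache$amax, B)
  dM <- pb$dM
  dHq <- pb$dHq                                 # through the interaction map
  dWo <- crossprod(cache$concat, dM)
  dconcat <- dM %*% t(params$Wo)
  dQp <- matrix(0, nrow(cache$Qp), C)
  dKp <- matrix(0, nrow(cache$Kp), C)
  dVp <- matrix(0, nrow(cache$Vp), C)
  for (i in seq_len(hN)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    hb <- attn_head_bwd_cpp(cache$A[[i]], cache$Qp[, cols, drop = FALSE],
                            cache$Kp[, cols, drop = FALSE],
                            cache$Vp[, cols, drop = FALSE],
                            dconcat[, cols, drop = FALSE], B)
    dQp[, cols] <- hb$dQp
    dKp[, cols] <- hb$dKp
    dVp[, cols] <- hb$dVp
  }
  dHq <- dHq + dQp %*% t(params$Wq) + dVp %*% t(params$Wv)
  dHk <- dKp %*% t(params$Wk)
  list(dHq = dHq, dHk = dHk,
       dWq = crossprod(Hq, dQp), dWk = crossprod(Hk, dKp),
       dWv = crossprod(Hq, dVp), dWo = dWo)
}

# row indices of samples `bi` in a stacked (n*P, Cin) sequence-form matrix
.seq_rows <- function(bi, P) {
  rep((bi - 1L) * P, each = P) + rep.int(seq_len(P), length(bi))
}

# full forward over a batch of encoded pairs (X1, X2 are (B, D) matrices,
# or pre-stacked (B*P, Cin) sequence-form matrices when seq_form = TRUE)
.learner_fwd <- function(params, X1, X2, cfg, P, Cin, train, run_stats,
                         seq_form = FALSE, conv_idx = NULL) {
  if (seq_form) {
    B <- nrow(X1) %/% P
    Xs <- rbind(X1, X2)
  } else {
    B <- nrow(X1)
    Xs <- rbind(to_seq_form(X1, P, Cin), to_seq_form(X2, P, Cin))
  }
  conv <- .conv_stack_fwd(Xs, params, cfg, 2L * B, P, train, run_stats,
                          conv_idx = conv_idx)
  run_stats$mean <- conv$run_stats$mean
  run_stats$var <- conv$run_stats$var
  H1 <- conv$out[seq_len(B * P), , drop = FALSE]
  H2 <- conv$out[B * P + seq_len(B * P), , drop = FALSE]
  a1 <- .attn_dir_fwd(H1, H2, params, cfg, B, P)   # S1' = attn(S1, S2, S1)
  a2 <- .attn_dir_fwd(H2, H1, params, cfg, B, P)   # S2' = attn(S2, S1, S2)
  S1p <- a1$pooled; S2p <- a2$pooled
  n1 <- sqrt(rowSums(S1p^2)); n2 <- sqrt(rowSums(S2p^2))
  denom <- n1 * n2
  cos <- ifelse(denom == 0, 0, rowSums(S1p * S2p) / denom)
  AS2 <- S2p %*% t(params$Abil)                    # row b: (A %*% s2_b)'
  bil <- rowSums(S1p * AS2)
  Z <- cbind(cos, bil, S1p, S2p)
  if (train) {
    mbn <- bn_fwd(Z, params$mgamma, params$mbeta)
    run_stats$merge_mean <- 0.9 * (run_stats$merge_mean %||% 0) + 0.1 * mbn$mu
    run_stats$merge_var <- 0.9 * (run_stats$merge_var %||% 1) + 0.1 * mbn$var
  } else {
    mbn <- list(out = bn_fwd_infer(Z, params$mgamma, params$mbeta,
                                   run_stats$merge_mean %||% rep(0, ncol(Z)),
                                   run_stats$merge_var %||% rep(1, ncol(Z))))
  }
  dcache <- list()
  hcur <- mbn$out
  for (j in seq_along(cfg$dense)) {
    dn <- dense_fwd(hcur, params[[paste0("dW", j)]], params[[paste0("db", j)]])
    rl <- relu_fwd(dn$out)
    dcache[[j]] <- list(dense = dn, relu = rl)
    hcur <- rl$out
  }
  out <- dense_fwd(hcur, params$dWout, params$dbout)
  rs_out <- conv$run_stats
  rs_out$merge_mean <- run_stats$merge_mean
  rs_out$merge_var <- run_stats$merge_var
  list(logits = out$out, B = B, conv = conv, H1 = H1, H2 = H2,
       a1 = a1, a2 = a2, S1p = S1p, S2p = S2p, n1 = n1, n2 = n2,
       cos = cos, Z = Z, mbn = mbn, dcache = dcache, outcache = out,
       run_stats = rs_out)
}

.learner_bwd <- function(dlogits, fw, params, cfg, P, Cin) {
  B <- fw$B
  grads <- list()
  dn <- dense_bwd(fw$outcache, params$dWout, dlogits)
  grads$dWout <- dn$dW; grads$dbout <- dn$db
  dh <- dn$dX
  for (j in rev(seq_along(cfg$dense))) {
    dh <- relu_bwd(fw$dcache[[j]]$relu, dh)
    dn <- dense_bwd(fw$dcache[[j]]$dense, params[[paste0("dW", j)]], dh)
    grads[[paste0("dW", j)]] <- dn$dW
    grads[[paste0("db", j)]] <- dn$db
    dh <- dn$dX
  }
  if (!is.null(fw$mbn$xhat)) {
    mb <- bn_bwd(fw$mbn, params$mgamma, dh)
    grads$mgamma <- mb$dgamma
    grads$mbeta <- mb$dbeta
    dh <- mb$dX
  }
  dcos <- dh[, 1]; dbil <- dh[, 2]
  twoP <- 2L * P
  dS1p <- dh[, 2 + seq_len(twoP), drop = FALSE]
  dS2p <- dh[, 2 + twoP + seq_len(twoP), drop = FALSE]
  # cosine term (gradient 0 for zero-norm representations)
  S1p <- fw$S1p; S2p <- fw$S2p
  nz <- fw$n1 > 0 & fw$n2 > 0
  gc <- ifelse(nz, dcos, 0)
  inv <- ifelse(nz, 1 / (fw$n1 * fw$n2), 0)
  inv1 <- ifelse(fw$n1 > 0, 1 / fw$n1^2, 0)
  inv2 <- ifelse(fw$n2 > 0, 1 / fw$n2^2, 0)
  dS1p <- dS1p + gc * (S2p * inv - fw$cos * S1p * inv1)
  dS2p <- dS2p + gc * (S1p * inv - fw$cos * S2p * inv2)
  # bilinear term
  dS1p <- dS1p + dbil * (S2p %*% t(params$Abil))
  dS2p <- dS2p + dbil * (S1p %*% params$Abil)
  grads$Abil <- crossprod(S1p * dbil, S2p)
  # attention directions
  b1 <- .attn_dir_bwd(dS1p, fw$a1, fw$H1, fw$H2, params, cfg, B, P)
  b2 <- .attn_dir_bwd(dS2p, fw$a2, fw$H2, fw$H1, params, cfg, B, P)
  grads$Wq <- b1$dWq + b2$dWq
  grads$Wk <- b1$dWk + b2$dWk
  grads$Wv <- b1$dWv + b2$dWv
  grads$Wo <- b1$dWo + b2$dWo
  dH1 <- b1$dHq + b2$dHk
  dH2 <- b2$dHq + b1$dHk
  # conv stack (shared weights across the pair)
  dHs <- rbind(dH1, dH2)
  k <- cfg$kernel; idx <- fw$conv$idx
  fc <- fw$conv$fconv
  cb <- conv_bwd(fc, params$fconvW, params$fconvb, idx, k, dHs,
                 nrow(dHs), cfg$channels)
  grads$fconvW <- cb$dW; grads$fconvb <- cb$db
  dcur <- cb$dX
  for (i in rev(seq_len(cfg$n_blocks))) {
    cc <- fw$conv$caches[[i]]
    dcur <- relu_bwd(cc$relu, dcur)
    bn <- bn_bwd(cc$bn, params[[paste0("gamma", i)]], dcur)
    grads[[paste0("gamma", i)]] <- bn$dgamma
    grads[[paste0("beta", i)]] <- bn$dbeta
    cb <- conv_bwd(cc$conv, params[[paste0("convW", i)]],
                   params[[paste0("convb", i)]], idx, k, bn$dX,
                   nrow(dcur), cc$cin)
    grads[[paste0("convW", i)]] <- cb$dW
    grads[[paste0("convb", i)]] <- cb$db
    dcur <- cb$dX
  }
  grads
}

# ---- training --------------------------------------------------------------

.pair_design <- function(pairs, features) {
  fid <- features$id
  unresolved <- setdiff(unique(c(pairs$idA, pairs$idB)), fid)
  if (length(unresolved) > 0) {
    stop("pair(s) reference proteins without features: ",
         paste(utils::head(unresolved, 5), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  rownames(mat) <- fid
  list(X1 = mat[pairs$idA, , drop = FALSE],
       X2 = mat[pairs$idB, , drop = FALSE])
}

.standardizer <- function(X1, X2) {
  both <- rbind(X1, X2)
  center <- colMeans(both)
  scale <- apply(both, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

.apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")
}

.pad_concat <- function(X, P, Cin) {
  need <- P * Cin - ncol(X)
  if (need > 0) X <- cbind(X, matrix(0, nrow(X), need))
  X
}

#' Train a basic pair learner
#'
#' Trains the convolution + attention + merge + dense classifier on encoded
#' protein pairs by softmax cross-entropy with Adam. Inputs are standardized
#' feature-wise using training-set statistics. When `val_fraction > 0`, a
#' stratified validation split drives early stopping (the weights with the
#' best validation loss are kept). Fully deterministic given `cfg$seed`.
#'
#' @param pairs A data frame of labelled pairs (`idA`, `idB`, `label`).
#' @param features A feature tibble from [encode_proteins()] covering every
#'   protein in `pairs`.
#' @param cfg A [learner_config()].
#' @return An object of class `ppi_learner` with a `predict()` method.
#' @export
train_basic <- function(pairs, features, cfg) {
  stopifnot(inherits(cfg, "ppi_learner_config"))
  assert_that(nrow(pairs) > 0, "`pairs` is empty")
  y <- as.integer(pairs$label)
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  des <- .pair_design(pairs, features)
  dims <- reshape_dims(cfg$technique, ncol(des$X1))
  P <- dims[["P"]]; Cin <- dims[["Cin"]]
  st <- .standardizer(des$X1, des$X2)
  X1 <- .pad_concat(.apply_standardizer(des$X1, st), P, Cin)
  X2 <- .pad_concat(.apply_standardizer(des$X2, st), P, Cin)

  X1s_all <- to_seq_form(X1, P, Cin)
  X2s_all <- to_seq_form(X2, P, Cin)
  if (isTRUE(cfg$symmetrize)) {
    tmp <- X1s_all
    X1s_all <- rbind(X1s_all, X2s_all)   # rows n+i are pair i swapped
    X2s_all <- rbind(X2s_all, tmp)
  }
  idx_cache <- new.env(parent = emptyenv())
  conv_idx_for <- function(B) {
    key <- as.character(B)
    if (is.null(idx_cache[[key]])) {
      idx_cache[[key]] <- conv_gather_index(2L * B, P, cfg$kernel)
    }
    idx_cache[[key]]
  }
  with_local_seed(cfg$seed, {
    n <- nrow(X1)
    val_idx <- integer(0)
    if (cfg$val_fraction > 0 && n >= 20) {
      val_idx <- unlist(lapply(c(0L, 1L), function(cl) {
        ids <- which(y == cl)
        sample(ids, max(1L, round(cfg$val_fraction * length(ids))))
      }))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (isTRUE(cfg$symmetrize)) {
      # both orientations of a training pair; validation keeps one
      tr_idx <- c(tr_idx, tr_idx + n)
      y <- c(y, y)
    }
    params <- init_learner_weights(cfg, P, Cin)
    run_stats <- list(mean = rep(list(rep(0, cfg$channels)), cfg$n_blocks),
                      var = rep(list(rep(1, cfg$channels)), cfg$n_blocks))
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, run_stats = run_stats,
                 epoch = 0L)
    wait <- 0L
    history <- numeric(0)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        if (length(bi) < 2) next    # batch normalization needs > 1 pair
        rows <- .seq_rows(bi, P)
        fw <- .learner_fwd(params, X1s_all[rows, , drop = FALSE],
                           X2s_all[rows, , drop = FALSE], cfg, P, Cin,
                           train = TRUE, run_stats = run_stats,
                           seq_form = TRUE, conv_idx = conv_idx_for(length(bi)))
        run_stats <- fw$run_stats
        sx <- softmax_xent(fw$logits, y[bi])
        grads <- .learner_bwd(sx$dlogits, fw, params, cfg, P, Cin)
        upd <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- upd$params; opt <- upd$state
      }
      if (length(val_idx) > 0) {
        vrows <- .seq_rows(val_idx, P)
        vf <- .learner_fwd(params, X1s_all[vrows, , drop = FALSE],
                           X2s_all[vrows, , drop = FALSE], cfg, P, Cin,
                           train = FALSE, run_stats = run_stats,
                           seq_form = TRUE,
                           conv_idx = conv_idx_for(length(val_idx)))
        vloss <- softmax_xent(vf$logits, y[val_idx])$loss
        history <- c(history, vloss)
        if (vloss < best$loss - 1e-6) {
          best <- list(loss = vloss, params = params, run_stats = run_stats,
                       epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      } else {
        best <- list(loss = NA_real_, params = params, run_stats = run_stats,
                     epoch = ep)
      }
    }
    if (is.finite(best$loss) || length(val_idx) == 0) {
      params <- best$params
      run_stats <- best$run_stats
    }
    structure(list(config = cfg, params = params, run_stats = run_stats,
                   standardizer = st, P = P, Cin = Cin,
                   n_features = ncol(des$X1),
                   val_history = history, best_epoch = best$epoch),
              class = "ppi_learner")
  })
}

#' Predict interaction probabilities with a basic learner
#'
#' @param object A fitted `ppi_learner`.
#' @param pairs A data frame with columns `idA`, `idB`.
#' @param features Feature tibble covering every protein in `pairs`.
#' @param ... Unused.
#' @return A tibble with columns `idA`, `idB`, `.pred_0`, `.pred_1`.
#' @export
predict.ppi_learner <- function(object, pairs, features, ...) {
  des <- .pair_design(pairs, features)
  assert_that(ncol(des$X1) == object$n_features,
              "feature width differs from the training features")
  X1 <- .pad_concat(.apply_standardizer(des$X1, object$standardizer),
                    object$P, object$Cin)
  X2 <- .pad_concat(.apply_standardizer(des$X2, object$standardizer),
                    object$P, object$Cin)
  n <- nrow(X1)
  fwd_probs <- function(A, B) {
    probs <- matrix(0, n, 2)
    for (start in seq(1, n, by = 512)) {
      bi <- start:min(start + 511, n)
      fw <- .learner_fwd(object$params, A[bi, , drop = FALSE],
                         B[bi, , drop = FALSE], object$config,
                         object$P, object$Cin, train = FALSE,
                         run_stats = object$run_stats)
      probs[bi, ] <- row_softmax(fw$logits)
    }
    probs
  }
  probs <- fwd_probs(X1, X2)
  if (isTRUE(object$config$symmetrize)) {
    probs <- (probs + fwd_probs(X2, X1)) / 2
  }
  tibble::tibble(idA = pairs$idA, idB = pairs$idB,
                 .pred_0 = probs[, 1], .pred_1 = probs[, 2])
}

#' @export
print.ppi_learner <- function(x, ...) {
  cat("<ppi_learner>", x$config$name, "\n")
  cat("  technique:", x$config$technique,
      " input:", x$n_features, "->", paste0("(", x$P, " x ", x$Cin, ")"), "\n")
  cat("  heads:", x$config$h, " dense:",
      paste(x$config$dense, collapse = "-"),
      " best epoch:", x$best_epoch, "\n")
  invisible(x)
}

# dispatch used by the stacking layer so tests can plug in stub learners
#' Fit a first-level learner (generic)
#'
#' Dispatches on the class of `cfg`; the shipped method trains a
#' [train_basic()] network. Test code can register additional methods (for
#' example, deterministic stubs) to exercise the stacking machinery.
#'
#' @param cfg A learner configuration object.
#' @param pairs Labelled pair table.
#' @param features Feature tibble for `cfg`'s technique.
#' @return A fitted learner understood by [predict_learner()].
#' @export
fit_learner <- function(cfg, pairs, features) UseMethod("fit_learner")

#' @export
fit_learner.ppi_learner_config <- function(cfg, pairs, features) {
  train_basic(pairs, features, cfg)
}

#' Positive-class probabilities from a fitted first-level learner (generic)
#'
#' @param model A fitted learner.
#' @param pairs Pair table to score.
#' @param features Feature tibble.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_learner <- function(model, pairs, features) UseMethod("predict_learner")

#' @export
predict_learner.ppi_learner <- function(model, pairs, features) {
  predict(model, pairs, features)$.pred_1
}
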