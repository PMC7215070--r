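# Minimal neural-network plumbing: parameter initialization, layer forward /
# backward passes on row-major batches, softmax cross-entropy, and Adam.
# Gradients are hand-derived and finite-difference-checked in the test suite.

# batched per-sample matmul over stacked blocks (see src/bmm.cpp)
bmm <- function(A, C, nb, mode = c("nn", "nt", "tn")) {
  mode <- match.arg(mode)
  bmm_cpp(A, C, as.integer(nb), match(mode, c("nn", "nt", "tn")) - 1L)
}

glorot_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# ---- dense -----------------------------------------------------------------

dense_fwd <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, "+"), X = X)
}

dense_bwd <- function(cache, W, dout) {
  list(dX = dout %*% t(W),
       dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

relu_fwd <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_bwd <- function(cache, dout) dout * cache$mask

# ---- batch normalization (per feature column) ------------------------------

bn_fwd <- function(X, gamma, beta, eps = 1e-5) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, invstd, "*")
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, invstd = invstd, mu = mu, var = v, n = n)
}

bn_fwd_infer <- function(X, gamma, beta, run_mean, run_var, eps = 1e-5) {
  xhat <- sweep(sweep(X, 2, run_mean), 2, 1 / sqrt(run_var + eps), "*")
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

bn_bwd <- function(cache, gamma, dout) {
  n <- cache$n
  dxhat <- sweep(dout, 2, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(
    sweep(n * dxhat, 2, s1) - sweep(cache$xhat, 2, s2, "*"),
    2, cache$invstd / n, "*"
  )
  list(dX = dX,
       dgamma = colSums(dout * cache$xhat),
       dbeta = colSums(dout))
}

# ---- 1-D convolution via im2col (same padding) -----------------------------

# X: (B*P, Cin) row-major batches; returns gather index rows (0 = zero pad)
conv_gather_index <- function(B, P, k) {
  half <- (k - 1L) %/% 2L
  offs <- seq_len(k) - 1L - half
  pos <- rep(seq_len(P), each = k) + rep(offs, P)     # (P*k) source positions
  valid <- pos >= 1L & pos <= P
  base <- rep((seq_len(B) - 1L) * P, each = P * k)
  idx <- base + rep(ifelse(valid, pos, 1L), B)
  idx[!rep(valid, B)] <- 0L                            # 0 marks padding
  idx
}

im2col <- function(X, idx, k) {
  Cin <- ncol(X)
  Xpad <- rbind(rep(0, Cin), X)                        # row 1 = zero pad
  cols <- Xpad[idx + 1L, , drop = FALSE]               # (B*P*k, Cin)
  # regroup so each output row holds the k taps side by side
  n_out <- length(idx) %/% k
  out <- matrix(0, n_out, k * Cin)
  for (t in seq_len(k)) {
    out[, ((t - 1L) * Cin + 1L):(t * Cin)] <-
      cols[seq(t, length(idx), by = k), , drop = FALSE]
  }
  out
}

conv_fwd <- function(X, W, b, idx, k) {
  Xcol <- im2col(X, idx, k)
  list(out = sweep(Xcol %*% W, 2, b, "+"), Xcol = Xcol)
}

conv_bwd <- function(cache, W, b, idx, k, dout, n_rows, Cin) {
  dW <- crossprod(cache$Xcol, dout)
  db <- colSums(dout)
  dXcol <- dout %*% t(W)                               # (B*P, k*Cin)
  dX <- matrix(0, n_rows, Cin)
  for (t in seq_len(k)) {
    idxt <- idx[seq(t, length(idx), by = k)]
    dst <- which(idxt > 0L)                            # source rows are unique
    src <- idxt[dst]                                   # within one tap
    dX[src, ] <- dX[src, ] +
      dXcol[dst, ((t - 1L) * Cin + 1L):(t * Cin), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- softmax ---------------------------------------------------------------

row_softmax <- function(X) {
  mx <- X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]
  e <- exp(X - mx)
  e / rowSums(e)
}

# mean cross-entropy over the batch; dlogits is the gradient wrt logits
softmax_xent <- function(logits, y01) {
  p <- row_softmax(logits)
  n <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y01 + 1L)] + eps))
  dlogits <- p
  dlogits[cbind(seq_len(n), y01 + 1L)] <-
    dlogits[cbind(seq_len(n), y01 + 1L)] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
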