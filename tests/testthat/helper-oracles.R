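# Independent brute-force transcriptions of the encoder and attention
# equations, written as literal loops so they share no code with the
# vectorized implementations they check.

oracle_property_matrix <- function(residues, props) {
  pm <- as.matrix(props[, setdiff(names(props), "aa")])
  rownames(pm) <- props$aa
  out <- matrix(NA_real_, length(residues), ncol(pm))
  for (i in seq_along(residues)) {
    if (residues[i] %in% rownames(pm)) {
      out[i, ] <- pm[residues[i], ]
    } else {
      out[i, ] <- colMeans(pm)
    }
  }
  out
}

# literal double-loop evaluation of the auto-covariance definition
oracle_ac <- function(seq, lag, props = aa_property_table()) {
  res <- strsplit(toupper(seq), "")[[1]]
  X <- oracle_property_matrix(res, props)
  L <- nrow(X); p <- ncol(X)
  out <- numeric(lag * p)
  pos <- 1
  for (lg in seq_len(lag)) {
    for (j in seq_len(p)) {
      mu <- sum(X[, j]) / L
      acc <- 0
      for (i in seq_len(L - lg)) {
        acc <- acc + (X[i, j] - mu) * (X[i + lg, j] - mu)
      }
      out[pos] <- acc / (L - lg)
      pos <- pos + 1
    }
  }
  out
}

# literal transcription of the pseudo-amino-acid composition equations
oracle_pseaac <- function(seq, lambda, omega = 0.05,
                          props = pseaac_property_table(),
                          squared = FALSE) {
  res <- strsplit(toupper(seq), "")[[1]]
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  std <- res[res %in% aa]
  f <- unname(sapply(aa, function(a) sum(std == a))) / length(std)
  H <- oracle_property_matrix(res, props)
  L <- length(res)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(L - j)) {
      J <- 0
      for (pp in seq_len(ncol(H))) {
        d <- H[i + j, pp] - H[i, pp]
        J <- J + (if (squared) d^2 else d)
      }
      acc <- acc + J / ncol(H)
    }
    theta[j] <- acc / (L - j)
  }
  denom <- sum(f) + omega * sum(theta)
  c(f, omega * theta) / denom
}

oracle_softmax_row <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# scaled dot-product attention, elementwise
oracle_attention <- function(Q, K, V) {
  n_q <- nrow(Q); n_k <- nrow(K); dk <- ncol(K)
  W <- matrix(0, n_q, n_k)
  for (i in seq_len(n_q)) {
    s <- numeric(n_k)
    for (j in seq_len(n_k)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    W[i, ] <- oracle_softmax_row(s)
  }
  out <- matrix(0, n_q, ncol(V))
  for (i in seq_len(n_q)) {
    for (e in seq_len(ncol(V))) out[i, e] <- sum(W[i, ] * V[, e])
  }
  list(weights = W, output = out)
}

oracle_multi_head <- function(Q, K, V, w) {
  heads <- NULL
  for (i in seq_along(w$Wq)) {
    o <- oracle_attention(Q %*% w$Wq[[i]], K %*% w$Wk[[i]],
                          V %*% w$Wv[[i]])$output
    heads <- cbind(heads, o)
  }
  heads %*% w$Wo
}

oracle_pooled_multi_head <- function(Q, K, V, w) {
  M <- oracle_multi_head(Q, K, V, w)
  G <- M %*% t(Q)
  avg <- numeric(nrow(G)); mx <- numeric(nrow(G))
  for (i in seq_len(nrow(G))) {
    avg[i] <- mean(G[i, ])
    mx[i] <- max(G[i, ])
  }
  c(avg, mx)
}

oracle_merge <- function(s1, s2, A) {
  n1 <- sqrt(sum(s1^2)); n2 <- sqrt(sum(s2^2))
  cos <- if (n1 == 0 || n2 == 0) 0 else sum(s1 * s2) / (n1 * n2)
  bil <- 0
  for (i in seq_along(s1)) for (j in seq_along(s2)) {
    bil <- bil + s1[i] * A[i, j] * s2[j]
  }
  c(cos, bil, s1, s2)
}

# brute-force AUC by counting concordant positive/negative pairs
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (n in neg) {
    acc <- acc + (p > n) + 0.5 * (p == n)
  }
  acc / (length(pos) * length(neg))
}

# random identity-style multi-head weight set for small tests
random_mh_weights <- function(d_in, h, dk, d_model = h * dk) {
  list(Wq = replicate(h, matrix(rnorm(d_in * dk), d_in), simplify = FALSE),
       Wk = replicate(h, matrix(rnorm(d_in * dk), d_in), simplify = FALSE),
       Wv = replicate(h, matrix(rnorm(d_in * dk), d_in), simplify = FALSE),
       Wo = matrix(rnorm(h * dk * d_model), h * dk))
}

random_aa_seq <- function(L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), L, replace = TRUE),
        collapse = "")
}
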