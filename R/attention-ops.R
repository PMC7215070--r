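# The building blocks of the pair classifier as pure, single-sample
# functions: convolution stack, scaled dot-product attention, multi-head
# attention, attention with pooling, and the pair-merge layer. The batched
# training path (learner.R) composes exactly these computations; the test
# suite checks both against independent brute-force transcriptions.

#' Convolution stack over a reshaped feature vector
#'
#' Applies `n_blocks` repetitions of convolution, batch normalization and
#' ReLU, followed by a closing convolution, to a `(positions x channels)`
#' matrix. Convolutions are 1-D with 'same' zero padding along the position
#' axis. `weights` is a list with elements `blocks` (a list of
#' `list(W, b, gamma, beta)`, where `W` is `(kernel*channels_in) x channels`)
#' and `final` (`list(W, b)`); see [init_learner_weights()] for the shapes
#' the trainer uses. Normalization statistics are taken over the positions of
#' `x` unless `bn_stats` (a list of `list(mean, var)` per block) is supplied.
#'
#' @param x Numeric matrix `(positions x channels_in)`.
#' @param weights Convolution weights as described above.
#' @param kernel Convolution width (odd, default 3).
#' @param bn_stats Optional fixed normalization statistics per block.
#' @return The output feature map, `(positions x channels_out)`.
#' @export
conv_stack <- function(x, weights, kernel = 3, bn_stats = NULL) {
  assert_that(is.matrix(x), "`x` must be a (positions x channels) matrix")
  P <- nrow(x)
  h <- x
  for (i in seq_along(weights$blocks)) {
    blk <- weights$blocks[[i]]
    expected <- kernel * ncol(h)
    if (nrow(blk$W) != expected) {
      stop("conv block ", i, ": weight rows ", nrow(blk$W),
           " but expected ", expected, " (kernel ", kernel, " x ", ncol(h),
           " input channels)", call. = FALSE)
    }
    idx <- conv_gather_index(1L, P, as.integer(kernel))
    h <- conv_fwd(h, blk$W, blk$b, idx, as.integer(kernel))$out
    if (is.null(bn_stats)) {
      h <- bn_fwd(h, blk$gamma, blk$beta)$out
    } else {
      h <- bn_fwd_infer(h, blk$gamma, blk$beta,
                        bn_stats[[i]]$mean, bn_stats[[i]]$var)
    }
    h <- pmax(h, 0)
  }
  idx <- conv_gather_index(1L, P, as.integer(kernel))
  conv_fwd(h, weights$final$W, weights$final$b, idx, as.integer(kernel))$out
}

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' / sqrt(d_k))` row-wise, `output = weights V`.
#'
#' @param Q Query matrix `(n_q x d_k)`.
#' @param K Key matrix `(n_kv x d_k)`.
#' @param V Value matrix `(n_kv x d_v)`.
#' @return A list with `weights` (`n_q x n_kv`, rows summing to 1) and
#'   `output` (`n_q x d_v`).
#' @export
#' @examples
#' scaled_dot_attention(diag(2), diag(2), matrix(1:4, 2))$weights
scaled_dot_attention <- function(Q, K, V) {
  assert_that(ncol(Q) == ncol(K), "Q and K must share the key width d_k")
  assert_that(nrow(K) == nrow(V), "K and V must have the same number of rows")
  W <- row_softmax(Q %*% t(K) / sqrt(ncol(K)))
  list(weights = W, output = W %*% V)
}

#' Multi-head attention
#'
#' Runs `h` scaled dot-product attentions on linearly projected queries, keys
#' and values and re-projects the concatenated heads. `weights` is a list
#' with `Wq`, `Wk`, `Wv` (each a list of `h` projection matrices,
#' `d_in x d_k`) and `Wo` (`h*d_k x d_model`).
#'
#' @param Q,K,V Input matrices; `Q` and `K` must share a width compatible
#'   with the projections, and `K`, `V` the same row count.
#' @param weights Projection weights as described above.
#' @return The attended representation, `nrow(Q) x ncol(weights$Wo)`.
#' @export
multi_head <- function(Q, K, V, weights) {
  h <- length(weights$Wq)
  assert_that(h >= 1 && length(weights$Wk) == h && length(weights$Wv) == h,
              "`weights` must hold h projection triples")
  heads <- lapply(seq_len(h), function(i) {
    scaled_dot_attention(Q %*% weights$Wq[[i]],
                         K %*% weights$Wk[[i]],
                         V %*% weights$Wv[[i]])$output
  })
  do.call(cbind, heads) %*% weights$Wo
}

#' Multi-head attention with average and max pooling
#'
#' Forms the interaction map `M Q'` between the multi-head output `M` and the
#' raw query `Q`, pools it over its last axis with both average and max
#' pooling, and concatenates the two pooled vectors. The result has fixed
#' length `2 * nrow(Q)` regardless of the key/value row count.
#'
#' @inheritParams multi_head
#' @return A numeric vector of length `2 * nrow(Q)`.
#' @export
pooled_multi_head <- function(Q, K, V, weights) {
  M <- multi_head(Q, K, V, weights)
  assert_that(ncol(M) == ncol(Q),
              "d_model must equal ncol(Q) to form the interaction map M Q'")
  G <- M %*% t(Q)
  c(rowMeans(G), apply(G, 1, max))
}

#' Merge-layer fusion of an attended protein pair
#'
#' Concatenates the cosine similarity of the two attended representations,
#' the bilinear interaction `S1' A S2`, and the two representations
#' themselves, giving a vector of length `2 * length(S1p) + 2`. A zero-norm
#' representation yields a cosine term of 0 rather than NaN.
#'
#' @param S1p,S2p Attended representations of the two proteins (equal
#'   length).
#' @param A Square interaction weight matrix of matching size.
#' @return A numeric vector of length `2 * length(S1p) + 2`.
#' @export
merge_pair <- function(S1p, S2p, A) {
  assert_that(length(S1p) == length(S2p),
              "S1p and S2p must have the same length")
  assert_that(is.matrix(A) && all(dim(A) == length(S1p)),
              "A must be a square matrix matching length(S1p)")
  n1 <- sqrt(sum(S1p^2)); n2 <- sqrt(sum(S2p^2))
  cos <- if (n1 == 0 || n2 == 0) 0 else sum(S1p * S2p) / (n1 * n2)
  bil <- as.numeric(t(S1p) %*% A %*% S2p)
  c(cosine = cos, bilinear = bil, S1p, S2p)
}
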