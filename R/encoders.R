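# Sequence feature encoders: auto covariance (AC), conjoint triad (CT),
# local descriptor (LD) and pseudo amino acid composition (PseAAC).
#
# All four map one amino-acid sequence to a fixed-length numeric vector:
# AC = 7 * lag, CT = 343, LD = 630, PseAAC = 20 + lambda. `encode_proteins()`
# is the tibble-in / tibble-out wrapper used by the modelling layer.

validate_sequence <- function(seq) {
  assert_that(is.character(seq) && length(seq) == 1 && !is.na(seq),
              "`seq` must be a single string")
  ch <- split_seq(toupper(seq))
  bad <- setdiff(unique(ch), c(AA_LETTERS, NONSTANDARD_LETTERS))
  if (length(bad) > 0) {
    stop("sequence contains non-amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ch
}

# L x p property matrix for a residue vector. Under "impute", ambiguous or
# unknown letters take the column mean of the table (0 when standardized);
# under "strict" they are an error naming the first offending position.
residue_property_matrix <- function(residues, props,
                                    nonstandard = c("impute", "strict")) {
  nonstandard <- match.arg(nonstandard)
  pm <- as.matrix(props[, setdiff(names(props), "aa"), drop = FALSE])
  rownames(pm) <- props$aa
  hit <- match(residues, rownames(pm))
  if (anyNA(hit)) {
    if (nonstandard == "strict") {
      pos <- which(is.na(hit))[1]
      stop("non-standard residue '", residues[pos], "' at position ", pos,
           " (nonstandard = \"strict\")", call. = FALSE)
    }
    out <- matrix(rep(colMeans(pm), each = length(residues)),
                  nrow = length(residues))
    ok <- !is.na(hit)
    out[ok, ] <- pm[hit[ok], , drop = FALSE]
  } else {
    out <- pm[hit, , drop = FALSE]
  }
  colnames(out) <- colnames(pm)
  out
}

#' Auto-covariance encoding of a protein sequence
#'
#' Encodes a sequence of length `L` as `lag * 7` values: for each lag
#' `1..lag` and each of the seven physicochemical properties, the mean over
#' positions `i = 1..L-lag` of the product of the centred property values at
#' positions `i` and `i + lag` (centring by the per-sequence property mean,
#' averaging by `1/(L - lag)`). Entries are lag-major: the 7 properties for
#' lag 1, then lag 2, and so on. With the default `lag = 30` the vector has
#' length 210.
#'
#' @param seq A single amino-acid string.
#' @param lag Maximum lag (default 30); the sequence must be longer than this.
#' @param props Property table, see [aa_property_table()].
#' @param nonstandard `"impute"` maps ambiguous residues to the property-column
#'   mean; `"strict"` raises an error.
#' @return A named numeric vector of length `lag * 7`.
#' @export
#' @examples
#' length(ac_encode(strrep("ACDEFGHIKLMNPQRSTVWY", 4)))
ac_encode <- function(seq, lag = 30, props = aa_property_table(),
                      nonstandard = c("impute", "strict")) {
  residues <- validate_sequence(seq)
  L <- length(residues)
  assert_that(lag >= 1, "`lag` must be >= 1")
  if (L <= lag) {
    stop("sequence length ", L, " must exceed the maximum lag ", lag,
         " (minimum length ", lag + 1, ")", call. = FALSE)
  }
  X <- residue_property_matrix(residues, props, nonstandard)
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  out <- matrix(0, nrow = lag, ncol = p)
  for (lg in seq_len(lag)) {
    out[lg, ] <- colSums(Xc[seq_len(L - lg), , drop = FALSE] *
                           Xc[(1 + lg):L, , drop = FALSE]) / (L - lg)
  }
  v <- as.numeric(t(out))
  names(v) <- paste0("AC_lag", sprintf("%02d", rep(seq_len(lag), each = p)),
                     "_", rep(colnames(X), lag))
  v
}

#' Map a sequence to its seven-group digit string
#'
#' Each residue is replaced by its group index 1-7 under the dipole /
#' side-chain-volume classification ([aa_group_map()]). Under the default
#' `"impute"` policy the ambiguity codes B, Z, U and J map to the group of
#' their most common resolution and O/X are dropped with a warning (so the
#' result can be shorter than the input); `"strict"` raises on any
#' non-standard residue.
#'
#' @inheritParams ac_encode
#' @return A string of digits 1-7 (possibly empty).
#' @export
#' @examples
#' ct_group("AGV") # "111"
ct_group <- function(seq, nonstandard = c("impute", "strict")) {
  paste(ct_group_ints(seq, nonstandard), collapse = "")
}

ct_group_ints <- function(seq, nonstandard = c("impute", "strict")) {
  nonstandard <- match.arg(nonstandard)
  residues <- validate_sequence(seq)
  if (length(residues) == 0 || identical(seq, "")) return(integer(0))
  g <- .aa_group[residues]
  if (anyNA(g)) {
    if (nonstandard == "strict") {
      pos <- which(is.na(g))[1]
      stop("residue '", residues[pos], "' at position ", pos,
           " has no amino-acid group (nonstandard = \"strict\")",
           call. = FALSE)
    }
    g[is.na(g)] <- .nonstandard_group[residues[is.na(g)]]
    if (anyNA(g)) {
      warning("dropping ", sum(is.na(g)),
              " residue(s) without a group assignment (O or X)")
      g <- g[!is.na(g)]
    }
  }
  unname(g)
}

#' Conjoint-triad encoding of a protein sequence
#'
#' Counts each of the 343 group triads (three consecutive residues under the
#' seven-group alphabet) over the `L - 2` sliding windows and normalizes by
#' `L - 2`, so the vector is a frequency distribution over triad types. Bin
#' `(g1, g2, g3)` sits at position `(g1-1)*49 + (g2-1)*7 + g3`. Boundary
#' pseudo-triads that pad beyond the sequence ends are not counted.
#'
#' @inheritParams ac_encode
#' @return A named numeric vector of length 343 summing to 1.
#' @export
ct_encode <- function(seq, nonstandard = c("impute", "strict")) {
  g <- ct_group_ints(seq, nonstandard)
  L <- length(g)
  if (L < 3) stop("need at least 3 groupable residues for conjoint triads, got ",
                  L, call. = FALSE)
  idx <- (g[1:(L - 2)] - 1L) * 49L + (g[2:(L - 1)] - 1L) * 7L + g[3:L]
  v <- tabulate(idx, nbins = 343L) / (L - 2)
  grid <- expand.grid(g3 = 1:7, g2 = 1:7, g1 = 1:7)[, 3:1]
  names(v) <- paste0("CT_", grid$g1, grid$g2, grid$g3)
  v
}

#' Split a sequence into the ten local-descriptor regions
#'
#' Regions A-D are the four quarters, E-F the two halves, G the central 50%,
#' H the first 75%, I the final 75% and J the central 75% of the sequence.
#' Cut points are floor-based (`floor(L*k/4)`, `floor(L/8)`, `floor(7L/8)`),
#' so concatenating A-D reconstructs the sequence exactly.
#'
#' @inheritParams ac_encode
#' @return A named character vector of the 10 subsequences `A` to `J`.
#' @export
#' @examples
#' nchar(ld_regions(strrep("A", 100)))
ld_regions <- function(seq) {
  assert_that(is.character(seq) && length(seq) == 1, "`seq` must be one string")
  L <- nchar(seq)
  if (L < 8) stop("local descriptors need sequences of length >= 8, got ", L,
                  call. = FALSE)
  q1 <- floor(L / 4); q2 <- floor(L / 2); q3 <- floor(3 * L / 4)
  e1 <- floor(L / 8); e7 <- floor(7 * L / 8)
  c(
    A = substr(seq, 1, q1),
    B = substr(seq, q1 + 1, q2),
    C = substr(seq, q2 + 1, q3),
    D = substr(seq, q3 + 1, L),
    E = substr(seq, 1, q2),
    F = substr(seq, q2 + 1, L),
    G = substr(seq, q1 + 1, q3),
    H = substr(seq, 1, q3),
    I = substr(seq, q1 + 1, L),
    J = substr(seq, e1 + 1, e7)
  )
}

.ld_pairs <- utils::combn(7, 2)

#' Composition/transition/distribution descriptor of one region
#'
#' For a subsequence of `n` groupable residues: composition is the frequency
#' of each of the 7 groups (`count / n`); transition is, for each of the 21
#' unordered group pairs, the fraction of the `n - 1` adjacent position pairs
#' whose groups form that pair; distribution gives, for each group with count
#' `c > 0`, five values locating where the first and the 25/50/75/100% of that
#' group's residues fall. The default `"count"` distribution variant is
#' count-index based: `1/n` then `floor(q*c + 0.5)/n` for q = 0.25, 0.5, 0.75,
#' 1; the `"positional"` variant reports the actual sequence position of the
#' `ceiling(q*c)`-th occurrence divided by `n`. Groups absent from the region
#' contribute five zeros. Total length 7 + 21 + 35 = 63.
#'
#' @param subseq One region's amino-acid string (at least 2 groupable residues).
#' @param ld_distribution `"count"` (count-index arithmetic) or `"positional"`.
#' @inheritParams ac_encode
#' @return A named numeric vector of length 63.
#' @export
ld_ctd <- function(subseq, ld_distribution = c("count", "positional"),
                   nonstandard = c("impute", "strict")) {
  ld_distribution <- match.arg(ld_distribution)
  g <- ct_group_ints(subseq, nonstandard)
  n <- length(g)
  if (n < 2) stop("region has fewer than 2 groupable residues (", n, ")",
                  call. = FALSE)
  counts <- tabulate(g, nbins = 7L)
  comp <- counts / n
  names(comp) <- paste0("C", 1:7)

  a <- g[-n]; b <- g[-1]
  lo <- pmin(a, b); hi <- pmax(a, b)
  trans <- numeric(21)
  names(trans) <- paste0("T", .ld_pairs[1, ], .ld_pairs[2, ])
  changed <- lo != hi
  if (any(changed)) {
    key <- paste0("T", lo[changed], hi[changed])
    tab <- table(key)
    trans[names(tab)] <- as.numeric(tab)
  }
  trans <- trans / (n - 1)

  qs <- c(0, 0.25, 0.5, 0.75, 1)
  dist <- numeric(35)
  names(dist) <- paste0("D", rep(1:7, each = 5), "_q",
                        rep(c("0", "25", "50", "75", "100"), 7))
  for (grp in 1:7) {
    cg <- counts[grp]
    if (cg == 0) next
    if (ld_distribution == "count") {
      vals <- c(1, floor(qs[-1] * cg + 0.5)) / n
    } else {
      pos <- which(g == grp)
      vals <- pos[pmax(1L, ceiling(qs * cg))] / n
    }
    dist[(grp - 1) * 5 + seq_len(5)] <- vals
  }
  c(comp, trans, dist)
}

#' Local-descriptor encoding of a protein sequence
#'
#' Concatenates the 63 composition/transition/distribution values of each of
#' the ten regions A-J ([ld_regions()], [ld_ctd()]), giving a 630-dimensional
#' vector.
#'
#' @inheritParams ld_ctd
#' @inheritParams ac_encode
#' @return A named numeric vector of length 630.
#' @export
ld_encode <- function(seq, ld_distribution = c("count", "positional"),
                      nonstandard = c("impute", "strict")) {
  regions <- ld_regions(toupper(seq))
  parts <- lapply(names(regions), function(r) {
    v <- ld_ctd(regions[[r]], ld_distribution, nonstandard)
    names(v) <- paste0("LD_", r, "_", names(v))
    v
  })
  unlist(parts)
}

#' Pseudo amino acid composition of a protein sequence
#'
#' The first 20 entries are the occurrence frequencies of the standard amino
#' acids; the last `lambda` entries are sequence-order correlation factors
#' `theta_j` (j = 1..lambda), each the average over the sequence of the mean
#' difference of three standardized properties (hydrophobicity,
#' hydrophilicity, side-chain mass) between residues `j` apart, weighted by
#' `omega`. All `20 + lambda` entries share the denominator
#' `sum(f) + omega * sum(theta)`, so the vector sums to 1. The default
#' correlation uses the plain property difference; `correlation = "squared"`
#' switches to the squared-difference convention.
#'
#' @inheritParams ac_encode
#' @param lambda Number of sequence-order terms (must be `< nchar(seq)`).
#' @param omega Weight of the sequence-order terms (default 0.05).
#' @param props Three-property table, see [pseaac_property_table()].
#' @param correlation `"signed"` (plain difference) or `"squared"`.
#' @return A named numeric vector of length `20 + lambda`.
#' @export
pseaac_encode <- function(seq, lambda = 15, omega = 0.05,
                          props = pseaac_property_table(),
                          correlation = c("signed", "squared"),
                          nonstandard = c("impute", "strict")) {
  correlation <- match.arg(correlation)
  assert_that(omega > 0, "`omega` must be > 0")
  assert_that(lambda >= 0, "`lambda` must be >= 0")
  residues <- validate_sequence(seq)
  L <- length(residues)
  if (lambda >= L) {
    stop("`lambda` (", lambda, ") must be smaller than the sequence length (",
         L, ")", call. = FALSE)
  }
  std <- residues[residues %in% AA_LETTERS]
  f <- tabulate(match(std, AA_LETTERS), nbins = 20L) / length(std)
  theta <- numeric(0)
  if (lambda > 0) {
    H <- residue_property_matrix(residues, props, nonstandard)
    theta <- vapply(seq_len(lambda), function(j) {
      d <- H[(1 + j):L, , drop = FALSE] - H[1:(L - j), , drop = FALSE]
      if (correlation == "squared") d <- d^2
      mean(rowMeans(d))
    }, numeric(1))
  }
  denom <- sum(f) + omega * sum(theta)
  v <- c(f, omega * theta) / denom
  names(v) <- c(paste0("PseAAC_f_", AA_LETTERS),
                if (lambda > 0) paste0("PseAAC_th", sprintf("%02d", seq_len(lambda))))
  v
}

#' Encode a table of proteins under one technique
#'
#' Tibble-in / tibble-out wrapper around the four sequence encoders: one row
#' per protein, one column per feature, first column `id`.
#'
#' @param records A data frame with columns `id` and `seq` (see
#'   [read_fasta()] or [simulate_proteome()]).
#' @param technique One of `"ac"`, `"ct"`, `"ld"`, `"pseaac"`.
#' @param lag,lambda,omega,ld_distribution,correlation,nonstandard Passed to
#'   the corresponding encoder.
#' @return A tibble of dimensions `nrow(records)` x `1 + d`.
#' @export
#' @examples
#' recs <- tibble::tibble(id = "p1", seq = strrep("ACDEFGHIKLMNPQRSTVWY", 4))
#' dim(encode_proteins(recs, "ct"))
encode_proteins <- function(records,
                            technique = c("ac", "ct", "ld", "pseaac"),
                            lag = 30, lambda = 15, omega = 0.05,
                            ld_distribution = c("count", "positional"),
                            correlation = c("signed", "squared"),
                            nonstandard = c("impute", "strict")) {
  technique <- match.arg(technique)
  assert_that(is.data.frame(records) && all(c("id", "seq") %in% names(records)),
              "`records` must have columns `id` and `seq`")
  enc <- switch(technique,
    ac = function(s) ac_encode(s, lag = lag, nonstandard = nonstandard),
    ct = function(s) ct_encode(s, nonstandard = nonstandard),
    ld = function(s) ld_encode(s, ld_distribution = ld_distribution,
                               nonstandard = nonstandard),
    pseaac = function(s) pseaac_encode(s, lambda = lambda, omega = omega,
                                       correlation = correlation,
                                       nonstandard = nonstandard)
  )
  rows <- lapply(records$seq, enc)
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(id = records$id), out)
  attr(out, "technique") <- technique
  out
}

#' Encode proteins under several techniques at once
#'
#' @inheritParams encode_proteins
#' @param techniques Character vector of technique names.
#' @return A named list of feature tibbles, one per technique.
#' @export
encode_feature_sets <- function(records,
                                techniques = c("ac", "ct", "ld", "pseaac"),
                                ...) {
  out <- lapply(techniques, function(t) encode_proteins(records, t, ...))
  names(out) <- techniques
  out
}

#' Concatenate feature sets into one wide table
#'
#' Builds the concatenated representation (AC + CT + LD + PseAAC side by
#' side) used by the concatenated-input ensemble variant.
#'
#' @param features A named list of feature tibbles sharing the same `id`s.
#' @return A single feature tibble.
#' @export
build_concat_features <- function(features) {
  assert_that(length(features) >= 1, "need at least one feature set")
  ids <- features[[1]]$id
  for (f in features) {
    assert_that(identical(f$id, ids), "feature sets must share identical ids")
  }
  mats <- lapply(features, function(f) f[, setdiff(names(f), "id"), drop = FALSE])
  dplyr::bind_cols(tibble::tibble(id = ids), mats, .name_repair = "minimal")
}
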