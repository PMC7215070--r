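# Dataset construction: positive-set filters (sequence length, pairwise
# identity redundancy) and negative sampling by subcellular localization.

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment identity: matches divided by the
#' alignment length including gap positions (PID1), as a fraction in [0, 1].
#' Alignment is done with `Biostrings::pairwiseAlignment()` under BLOSUM62
#' with affine gap penalties.
#'
#' @param seq1,seq2 Amino-acid strings.
#' @return Identity in `[0, 1]`.
#' @export
seq_identity <- function(seq1, seq2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq1)), Biostrings::AAString(toupper(seq2)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 4
  )
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Filter a positive interaction set by length and sequence redundancy
#'
#' Removes every pair in which either protein is shorter than `min_len`
#' (default 50 residues). If `max_identity` is given, proteins are then
#' de-redundified greedily in first-seen order: a protein whose global
#' alignment identity ([seq_identity()]) to an already-retained protein
#' exceeds `max_identity` is dropped together with all its pairs, the earlier
#' protein acting as the representative. The identity filter defaults to off
#' (`NULL`) because it is expensive and synthetic data is non-redundant by
#' construction.
#'
#' @param records Protein tibble with columns `id`, `seq`.
#' @param pairs A data frame of pairs (`idA`, `idB`, `label`), all labelled 1.
#' @param min_len Minimum sequence length (default 50).
#' @param max_identity Redundancy threshold in `(0, 1]`, or `NULL` to skip.
#' @return A `ppi_pairs` tibble of the surviving pairs.
#' @export
filter_positive_set <- function(records, pairs, min_len = 50,
                                max_identity = NULL) {
  assert_that(min_len >= 1, "`min_len` must be >= 1")
  if (!is.null(max_identity)) {
    assert_that(max_identity > 0 && max_identity <= 1,
                "`max_identity` must be in (0, 1]")
  }
  pairs <- pair_dataset(pairs, provenance = attr(pairs, "provenance") %||%
                          "positive set")
  unresolved <- setdiff(unique(c(pairs$idA, pairs$idB)), records$id)
  if (length(unresolved) > 0) {
    stop("pair(s) reference unknown protein id(s): ",
         paste(utils::head(unresolved, 10), collapse = ", "), call. = FALSE)
  }
  len <- stats::setNames(nchar(records$seq), records$id)
  keep <- len[pairs$idA] >= min_len & len[pairs$idB] >= min_len
  pairs <- pairs[keep, ]

  if (!is.null(max_identity) && nrow(pairs) > 0) {
    used <- records$id[records$id %in% unique(c(pairs$idA, pairs$idB))]
    seqs <- stats::setNames(records$seq, records$id)[used]
    retained <- character(0)
    dropped <- character(0)
    for (id in used) {  # first-seen representative retention
      redundant <- FALSE
      for (rep_id in retained) {
        if (seq_identity(seqs[[id]], seqs[[rep_id]]) > max_identity) {
          redundant <- TRUE
          break
        }
      }
      if (redundant) dropped <- c(dropped, id) else retained <- c(retained, id)
    }
    if (length(dropped) > 0) {
      pairs <- pairs[!(pairs$idA %in% dropped | pairs$idB %in% dropped), ]
    }
  }
  pair_dataset(pairs, provenance = "filtered positive set")
}

#' Sample non-interacting pairs by differing subcellular localization
#'
#' Draws `round(ratio * nrow(positives))` negative pairs such that (1) the
#' two proteins of every pair carry different localization labels, (2) no
#' sampled pair occurs in the positive set, and (3) no protein is used more
#' than `per_protein_cap` times, which keeps the contribution of individual
#' proteins to the negative set balanced. The default cap is
#' `ceiling(2 * n_negatives / n_proteins)`. Sampling scans a seeded random
#' permutation of all eligible cross-localization pairs, so results are
#' reproducible for a fixed seed.
#'
#' @param records Protein tibble with columns `id`, `seq`, `localization`.
#' @param positives A data frame of positive pairs.
#' @param ratio Negative:positive ratio (default 1).
#' @param per_protein_cap Maximum occurrences per protein, or `NULL` for the
#'   default cap.
#' @param seed Integer seed for reproducible sampling.
#' @return A `ppi_pairs` tibble of negatives (label 0).
#' @export
sample_negatives <- function(records, positives, ratio = 1,
                             per_protein_cap = NULL, seed = 1) {
  assert_that(ratio > 0, "`ratio` must be > 0")
  assert_that("localization" %in% names(records) &&
                !anyNA(records$localization),
              "`records` must carry localization labels for every protein")
  n_neg <- round(ratio * nrow(positives))
  if (is.null(per_protein_cap)) {
    per_protein_cap <- ceiling(2 * n_neg / nrow(records))
  }
  assert_that(per_protein_cap >= 1, "`per_protein_cap` must be >= 1")

  n <- nrow(records)
  assert_that(n >= 2, "need at least two proteins")
  loc <- records$localization
  ids <- records$id
  # all unordered candidate pairs with differing localization
  idx <- which(outer(loc, loc, "!="), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  if (nrow(idx) == 0) {
    stop("no cross-localization pair exists: all proteins share one ",
         "localization", call. = FALSE)
  }
  cand_a <- ids[idx[, 1]]
  cand_b <- ids[idx[, 2]]
  pos_key <- pair_key(positives$idA, positives$idB)
  ok <- !(pair_key(cand_a, cand_b) %in% pos_key)
  cand_a <- cand_a[ok]; cand_b <- cand_b[ok]

  perm <- with_local_seed(seed, sample.int(length(cand_a)))
  usage <- stats::setNames(integer(n), ids)
  take <- logical(length(perm))
  got <- 0L
  for (j in perm) {
    a <- cand_a[j]; b <- cand_b[j]
    if (usage[[a]] < per_protein_cap && usage[[b]] < per_protein_cap) {
      take[j] <- TRUE
      usage[[a]] <- usage[[a]] + 1L
      usage[[b]] <- usage[[b]] + 1L
      got <- got + 1L
      if (got == n_neg) break
    }
  }
  if (got < n_neg) {
    stop("negative sampling infeasible: requested ", n_neg,
         " cross-localization pairs but only ", got,
         " are achievable under the per-protein cap of ", per_protein_cap,
         call. = FALSE)
  }
  pair_dataset(
    tibble::tibble(idA = cand_a[take], idB = cand_b[take], label = 0L),
    provenance = sprintf("localization-based negatives (seed %s)", seed)
  )
}

#' Combine positive and negative pair sets
#'
#' Binds the two sets, asserting that they are disjoint as unordered pairs.
#'
#' @param positives,negatives `ppi_pairs` tibbles.
#' @return A `ppi_pairs` tibble with both labels.
#' @export
bind_pair_sets <- function(positives, negatives) {
  inter <- intersect(pair_key(positives$idA, positives$idB),
                     pair_key(negatives$idA, negatives$idB))
  assert_that(length(inter) == 0,
              "positive and negative sets overlap as unordered pairs")
  pair_dataset(dplyr::bind_rows(positives, negatives),
               provenance = "positives + negatives")
}
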