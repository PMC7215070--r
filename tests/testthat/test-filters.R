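# Positive-set filtering and localization-based negative sampling.

make_filter_fixture <- function() {
  withr::with_seed(7, {
    tibble::tibble(
      id = sprintf("F%02d", 1:8),
      seq = c(random_aa_seq(49), random_aa_seq(60), random_aa_seq(70),
              random_aa_seq(80), random_aa_seq(90), random_aa_seq(100),
              random_aa_seq(55), random_aa_seq(65)),
      localization = c("nucleus", "cytoplasm", "nucleus", "mitochondrion",
                       "cytoplasm", "vacuole", "nucleus", "peroxisome")
    )
  })
}

test_that("pairs with short proteins are removed at the length threshold", {
  recs <- make_filter_fixture()   # F01 has 49 residues
  pairs <- tibble::tibble(idA = c("F01", "F02", "F03"),
                          idB = c("F02", "F03", "F04"),
                          label = 1L)
  kept <- filter_positive_set(recs, pairs, min_len = 50)
  expect_equal(nrow(kept), 2)
  expect_false("F01" %in% c(kept$idA, kept$idB))
  # all proteins long enough, identity filter off: unchanged
  kept2 <- filter_positive_set(recs, pairs[-1, ], min_len = 50)
  expect_equal(nrow(kept2), 2)
  # idempotence
  again <- filter_positive_set(recs, kept, min_len = 50)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(kept))
})

test_that("unresolved pair ids are reported", {
  recs <- make_filter_fixture()
  pairs <- tibble::tibble(idA = "F02", idB = "FXX", label = 1L)
  expect_error(filter_positive_set(recs, pairs), "FXX")
})

test_that("identical sequences are de-redundified at 40% identity", {
  recs <- make_filter_fixture()
  recs$seq[4] <- recs$seq[3]      # F04 duplicates F03 (identity 1 > 0.4)
  pairs <- tibble::tibble(idA = c("F02", "F03", "F04"),
                          idB = c("F03", "F05", "F06"),
                          label = 1L)
  expect_equal(seq_identity(recs$seq[3], recs$seq[4]), 1)
  kept <- filter_positive_set(recs, pairs, min_len = 50, max_identity = 0.4)
  # first-seen representative F03 is retained, F04 and its pairs dropped
  expect_true("F03" %in% c(kept$idA, kept$idB))
  expect_false("F04" %in% c(kept$idA, kept$idB))
  expect_equal(nrow(kept), 2)
})

test_that("negative sampling honours localization, exclusion and the cap", {
  recs <- make_filter_fixture()
  pos <- pair_dataset(tibble::tibble(
    idA = c("F02", "F03", "F04", "F05"),
    idB = c("F03", "F04", "F05", "F06"), label = 1L))
  neg <- sample_negatives(recs, pos, ratio = 1, seed = 42)
  expect_equal(nrow(neg), 4)
  expect_true(all(neg$label == 0))
  loc <- stats::setNames(recs$localization, recs$id)
  expect_true(all(loc[neg$idA] != loc[neg$idB]))
  # disjoint from positives as unordered pairs
  expect_length(intersect(paste(neg$idA, neg$idB), paste(pos$idA, pos$idB)), 0)
  # reproducibility and seed sensitivity
  expect_identical(tibble::as_tibble(sample_negatives(recs, pos, seed = 42)),
                   tibble::as_tibble(neg))
  # ratio scaling
  expect_equal(nrow(sample_negatives(recs, pos, ratio = 0.5, seed = 1)), 2)
})

test_that("the per-protein cap bounds every protein's contribution", {
  recs <- make_filter_fixture()
  pos <- pair_dataset(tibble::tibble(idA = "F02", idB = "F03", label = 1L))
  for (seed in 1:5) {
    neg <- sample_negatives(recs, pos, ratio = 5, per_protein_cap = 2,
                            seed = seed)
    usage <- table(c(neg$idA, neg$idB))
    expect_lte(max(usage), 2)
    expect_equal(nrow(neg), 5)
  }
  # cap of 1: every protein used at most once
  neg1 <- sample_negatives(recs, pos, ratio = 3, per_protein_cap = 1, seed = 2)
  expect_lte(max(table(c(neg1$idA, neg1$idB))), 1)
})

test_that("infeasible negative sampling errors with the achievable count", {
  recs <- make_filter_fixture()
  recs$localization <- "nucleus"
  pos <- pair_dataset(tibble::tibble(idA = "F02", idB = "F03", label = 1L))
  expect_error(sample_negatives(recs, pos, seed = 1),
               "no cross-localization pair")
  recs2 <- make_filter_fixture()
  pos2 <- pair_dataset(tibble::tibble(idA = "F02", idB = "F03", label = 1L))
  expect_error(
    sample_negatives(recs2, pos2, ratio = 50, per_protein_cap = 1, seed = 1),
    "achievable"
  )
})

test_that("positive and negative sets stay disjoint when bound", {
  recs <- make_filter_fixture()
  pos <- pair_dataset(tibble::tibble(idA = c("F02", "F04"),
                                     idB = c("F03", "F05"), label = 1L))
  neg <- sample_negatives(recs, pos, seed = 3)
  both <- bind_pair_sets(pos, neg)
  expect_equal(nrow(both), 4)
  expect_setequal(both$label, c(0L, 1L))
  fake <- neg
  fake$idA[1] <- pos$idA[1]; fake$idB[1] <- pos$idB[1]
  expect_error(bind_pair_sets(pos, pair_dataset(fake)), "overlap")
})
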