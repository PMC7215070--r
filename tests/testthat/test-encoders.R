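# Sequence encoders: printed worked examples, dimension contracts, and
# brute-force oracle equivalence.

test_that("local descriptor reproduces the published worked arithmetic", {
  # 26-residue region with group counts 9 (A/G/V), 7 (C), 10 (F/I/L/P)
  s <- "ACLACLCCLAALLCCCLALALAAALL"
  v <- ld_ctd(s)
  expect_equal(unname(v[c("C1", "C2", "C3")]), c(9, 7, 10) / 26,
               tolerance = 1e-12)
  expect_equal(unname(v[c("C1", "C2", "C3")]), c(0.3461, 0.2693, 0.3846),
               tolerance = 1e-3)
  # distribution of group 1 (count 9): 1/26, then floor(q*9 + 0.5)/26
  expect_equal(unname(v[paste0("D1_q", c("0", "25", "50", "75", "100"))]),
               c(1, 2, 5, 7, 9) / 26, tolerance = 1e-12)
  expect_equal(unname(v[paste0("D1_q", c("25", "50", "75", "100"))]),
               c(0.0769, 0.1923, 0.2692, 0.3462), tolerance = 1e-3)
  # the printed transition ratios on a region whose adjacent group-pair
  # counts are exactly 2 (1-2), 3 (1-3) and 6 (2-3) out of 25
  groups <- c(1, 2, 1, 3, 2, 3, 2, 3, 2, 3, 1, 3, rep(3, 14))
  st <- paste(c("A", "C", "L")[groups], collapse = "")
  vt <- ld_ctd(st)
  expect_equal(unname(vt[c("T12", "T13", "T23")]), c(0.08, 0.12, 0.24),
               tolerance = 1e-12)
})

test_that("conjoint triads follow the sliding-window worked example", {
  # "CDKCCMD" maps to the grouped string "2762247"
  expect_equal(ct_group("CDKCCMD"), "2762247")
  v <- ct_encode("CDKCCMD")
  nz <- names(v[v > 0])
  expect_setequal(nz, paste0("CT_", c("276", "762", "622", "224", "247")))
  expect_equal(unname(v[nz]), rep(1 / 5, 5))
})

test_that("group mapping covers the seven-group table", {
  expect_equal(ct_group("AGV"), "111")
  expect_equal(ct_group("DECK"), "7726")
  expect_equal(ct_group(""), "")
  gm <- aa_group_map()
  expect_equal(nrow(gm), 20)
  expect_setequal(gm$group, 1:7)
  expect_equal(sum(gm$group == 1), 3)  # A, G, V
  expect_equal(gm$group[gm$aa == "C"], 2)
})

test_that("encoders produce constant dimensions regardless of input length", {
  withr::with_seed(11, {
    for (L in c(40, 61, 128, 333)) {
      s <- random_aa_seq(L)
      expect_length(ac_encode(s), 210)
      expect_length(ct_encode(s), 343)
      expect_length(ld_encode(s), 630)
      expect_length(pseaac_encode(s, lambda = 15), 35)
      expect_length(pseaac_encode(s, lambda = 4), 24)
    }
  })
})

test_that("region splitting uses floor-based cut points", {
  expect_equal(unname(nchar(ld_regions(strrep("A", 100)))),
               c(25, 25, 25, 25, 50, 50, 50, 75, 75, 75))
  expect_equal(unname(nchar(ld_regions(strrep("A", 8)))[1:4]), rep(2, 4))
  expect_equal(unname(nchar(ld_regions(strrep("A", 26)))[1:4]), c(6, 7, 6, 7))
  s <- random_aa_seq(53)
  r <- ld_regions(s)
  expect_identical(paste0(r[["A"]], r[["B"]], r[["C"]], r[["D"]]), s)
  expect_error(ld_regions(strrep("A", 7)), "length >= 8")
})

test_that("auto covariance matches a literal double-loop oracle", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      L <- sample(40:120, 1)
      lg <- sample(3:8, 1)
      s <- random_aa_seq(L)
      expect_equal(unname(ac_encode(s, lag = lg)), oracle_ac(s, lg),
                   tolerance = 1e-12)
    }
  })
  # the worked-dimension case: 20-letter alphabet repeated past length 62
  s62 <- substr(strrep("ACDEFGHIKLMNPQRSTVWY", 4), 1, 62)
  expect_equal(unname(ac_encode(s62, lag = 1))[1],
               oracle_ac(s62, 1)[1], tolerance = 1e-12)
})

test_that("auto covariance is zero on homopolymers and shift-invariant", {
  expect_equal(max(abs(ac_encode(strrep("A", 100)))), 0)
  # adding a constant to a property column must not change the encoding
  props <- aa_property_table(standardized = FALSE)
  shifted <- props
  shifted$H1 <- shifted$H1 + 100
  s <- random_aa_seq(80)
  expect_equal(ac_encode(s, props = props), ac_encode(s, props = shifted),
               tolerance = 1e-9)
  expect_error(ac_encode(random_aa_seq(30), lag = 30), "minimum length 31")
})

test_that("conjoint-triad frequencies are a distribution", {
  withr::with_seed(31, {
    for (rep in 1:4) {
      v <- ct_encode(random_aa_seq(sample(30:200, 1)))
      expect_true(all(v >= 0))
      expect_equal(sum(v), 1, tolerance = 1e-12)
    }
  })
  vh <- ct_encode(strrep("A", 10))
  expect_equal(unname(vh["CT_111"]), 1)
  expect_equal(sum(vh > 0), 1)
  expect_error(ct_encode("AC"), "at least 3")
})

test_that("local descriptor concatenates per-region blocks in order", {
  s <- random_aa_seq(90)
  v <- ld_encode(s)
  expect_length(v, 630)
  # per-region composition sums to 1
  for (r in c("A", "E", "J")) {
    expect_equal(sum(v[paste0("LD_", r, "_C", 1:7)]), 1, tolerance = 1e-12)
  }
  quarter <- ld_regions(s)[["A"]]
  expect_equal(unname(v[1:63]), unname(ld_ctd(quarter)))
  # positional distribution variant stays in (0, 1] and differs in general
  vp <- ld_encode(s, ld_distribution = "positional")
  expect_length(vp, 630)
  expect_true(all(vp >= 0 & vp <= 1))
})

test_that("pseudo amino acid composition matches its literal transcription", {
  withr::with_seed(41, {
    for (rep in 1:6) {
      L <- sample(30:120, 1)
      lam <- sample(2:10, 1)
      s <- random_aa_seq(L)
      expect_equal(unname(pseaac_encode(s, lambda = lam)),
                   oracle_pseaac(s, lam), tolerance = 1e-12)
      expect_equal(sum(pseaac_encode(s, lambda = lam)), 1, tolerance = 1e-12)
      expect_equal(unname(pseaac_encode(s, lambda = lam,
                                        correlation = "squared")),
                   oracle_pseaac(s, lam, squared = TRUE), tolerance = 1e-12)
    }
  })
  s <- "ACDEFGHIKLMNPQRSTVWY"
  v0 <- pseaac_encode(s, lambda = 0)
  expect_equal(unname(v0), rep(1 / 20, 20))
  vh <- pseaac_encode(strrep("G", 50), lambda = 5)
  expect_equal(sum(vh > 0), 1)            # theta vanish on a homopolymer
  expect_equal(unname(vh["PseAAC_f_G"]), 1)
  expect_error(pseaac_encode("ACDEF", lambda = 5), "smaller than")
})

test_that("non-standard residues follow the declared policies", {
  expect_error(ct_group("ACX", nonstandard = "strict"), "position 3")
  expect_equal(ct_group("AB"), "17")      # B resolves to the D/E group
  expect_equal(ct_group("AZ"), "17")
  expect_equal(ct_group("AU"), "12")
  expect_warning(g <- ct_group("AXA"), "dropping")
  expect_equal(g, "11")
  # imputed residues take the property-column mean (0 after standardization)
  v1 <- ac_encode(paste0(strrep("ACDE", 20), "X"), lag = 3)
  expect_true(all(is.finite(v1)))
  expect_error(ac_encode(paste0(strrep("ACDE", 20), "X"), lag = 3,
                         nonstandard = "strict"), "position 81")
  expect_error(ac_encode("AC1D"), "non-amino-acid")
})

test_that("encode_proteins returns a tidy feature table", {
  recs <- tibble::tibble(id = c("p1", "p2"),
                         seq = c(random_aa_seq(70), random_aa_seq(90)))
  ft <- encode_proteins(recs, "ct")
  expect_s3_class(ft, "tbl_df")
  expect_equal(dim(ft), c(2, 344))
  expect_equal(ft$id, c("p1", "p2"))
  fl <- encode_feature_sets(recs, c("ac", "pseaac"), lambda = 5)
  expect_named(fl, c("ac", "pseaac"))
  cc <- build_concat_features(fl)
  expect_equal(ncol(cc), 1 + 210 + 25)
})
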