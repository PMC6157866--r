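test_that("the strong-binder boundary is inclusive at the threshold", {
  expect_equal(classify_binder(151.47, 500), "strong")
  expect_equal(classify_binder(14485.65, 500), "weak")
  expect_equal(classify_binder(500, 500), "strong")
  expect_equal(classify_binder(500.01, 500), "weak")
  expect_error(classify_binder(-1, 500), "positive")
})

test_that("the database-screen profile retains all eight mutant rows", {
  panel <- apc_mutation_panel()
  cand <- prioritize_pairs(panel, priority_config())
  expect_equal(nrow(cand), 8L)
  expect_equal(cand$mut_peptide[1], "SVLLVLTLK")
  expect_equal(cand$allele[1], "A*11:01")
  expect_equal(cand$mut_affinity_nm[1], 13.71)
  expect_equal(cand$rank, 1:8)
  expect_true(all(diff(cand$mut_affinity_nm) >= 0))
  # exactly one wildtype counterpart is itself a strong binder
  expect_equal(sum(classify_binder(panel$wt_affinity_nm, 500) == "strong"), 1L)
  expect_equal(panel$wt_peptide[panel$wt_affinity_nm <= 500], "IPSSQKQSF")
})

test_that("the family profile keeps only the differential strong binder", {
  fx <- apc_example()
  pairs <- enumerate_pairs(fx$wt_protein, fx$mut_protein, k = 9)
  scored <- suppressWarnings(
    score_pairs(pairs, c("B*35:01", "C*03:03"), scorer_table(table3_scores())))
  cand <- prioritize_pairs(scored, family_profile())
  expect_equal(unique(cand$mut_peptide), "QATEAERSF")
  expect_equal(unique(cand$wt_peptide), "QATEAERSS")
  expect_equal(nrow(cand), 2L) # one pair, presented at both alleles
  expect_equal(cand$allele, c("B*35:01", "C*03:03"))
  # the printed affinity differential passes a tenfold ratio comfortably
  expect_true(all(cand$wt_mut_ratio > 10))
  expect_equal(cand$wt_mut_ratio[1], 14485.65 / 151.47, tolerance = 1e-12)
})

test_that("empty input prioritizes to empty output", {
  empty <- apc_mutation_panel()[0, ]
  out <- prioritize_pairs(empty, priority_config())
  expect_equal(nrow(out), 0L)
  expect_true(all(c("rank", "passed_filters") %in% names(out)))
})

test_that("tightening the affinity threshold never enlarges the retained set", {
  set.seed(31)
  for (i in 1:25) {
    tbl <- random_scored_table(60)
    thresholds <- sort(10^runif(5, 0.5, 4.5))
    kept <- lapply(thresholds, function(th) {
      got <- prioritize_pairs(tbl, priority_config(affinity_max_nm = th,
                                                   require_tcr_positive = FALSE))
      paste(got$mut_peptide, got$allele, got$mut_affinity_nm)
    })
    for (j in seq_len(length(kept) - 1)) {
      expect_true(all(kept[[j]] %in% kept[[j + 1]]))
    }
  }
})

test_that("prioritization matches a brute-force filter on random tables", {
  set.seed(77)
  for (i in 1:20) {
    tbl <- random_scored_table(40)
    max_nm <- 10^runif(1, 1, 4)
    need_tcr <- runif(1) < 0.5
    ratio <- sample(c(0, 2, 10), 1)
    got <- prioritize_pairs(tbl, priority_config(max_nm, need_tcr, ratio))
    want <- oracle_filter(tbl, max_nm, need_tcr, ratio)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$mut_peptide, got$allele, got$mut_affinity_nm),
                    paste(want$mut_peptide, want$allele, want$mut_affinity_nm))
  }
})

test_that("donor restriction keeps alleles the donor carries", {
  geno <- table2_hla()
  iv9 <- geno[geno$donor_id == "IV.9", ]
  iv2 <- geno[geno$donor_id == "IV.2", ]
  cand <- prioritize_pairs(apc_mutation_panel(), priority_config())

  b35 <- cand[cand$key == "B*35:01", ]
  expect_gt(nrow(b35), 0)
  expect_equal(nrow(hla_restrict(b35, iv9)), nrow(b35)) # IV.9 has B*35:01:01:02

  # IV.2 lacks C*03:03: a C*03:03 candidate is dropped
  c0303 <- tibble::tibble(mut_peptide = "QATEAERSF", allele = "C*03:03",
                          key = "C*03:03", mut_affinity_nm = 621.64)
  expect_equal(nrow(hla_restrict(c0303, iv2)), 0L)
  # identity match
  a11 <- cand[cand$key == "A*11:01", ]
  expect_equal(nrow(hla_restrict(a11, hla_genotype("d", "A*11:01"))), nrow(a11))
})

test_that("restriction is idempotent and commutes with prioritization", {
  set.seed(13)
  geno <- table2_hla()
  iv9 <- geno[geno$donor_id == "IV.9", ]
  tbl <- random_scored_table(80)
  cfg <- priority_config(require_tcr_positive = FALSE)

  once <- hla_restrict(prioritize_pairs(tbl, cfg), iv9)
  twice <- hla_restrict(once, iv9)
  expect_equal(as.data.frame(once), as.data.frame(twice))

  other <- prioritize_pairs(hla_restrict(tbl, iv9), cfg)
  expect_setequal(paste(once$mut_peptide, once$allele, once$mut_affinity_nm),
                  paste(other$mut_peptide, other$allele, other$mut_affinity_nm))
})
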