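test_that("generated coding sequences are reproducible and well-formed", {
  cfg <- sim_config(seed = 1, n_codons = 100)
  cds1 <- gen_cds(cfg)
  cds2 <- gen_cds(cfg)
  expect_identical(cds1, cds2)
  cds <- unname(cds1)
  expect_equal(nchar(cds), 300L)
  expect_equal(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, 298, 300) %in% c("TAA", "TAG", "TGA"))
  prot <- translate_cds(cds, require_start = TRUE)
  expect_equal(nchar(prot), 99L) # stops only at the terminal codon
  expect_false(attr(prot, "no_stop"))
})

test_that("generated CDSs pass stop and frameshift-termination scans", {
  for (seed in 1:100) {
    cfg <- sim_config(seed = seed, n_codons = 60)
    cds <- unname(gen_cds(cfg))
    # no internal in-frame stop (independent scan)
    codons <- substring(cds, seq(1, nchar(cds) - 3, 3),
                        seq(3, nchar(cds) - 1, 3))
    internal <- codons[seq_len(length(codons) - 1)]
    expect_false(any(internal %in% c("TAA", "TAG", "TGA")))
    expect_true(fs_termination_ok(cds, cfg$fs_max_extension))
  }
})

test_that("generated variants are deterministic and frameshifts frameshift", {
  cfg <- sim_config(seed = 5, n_codons = 80, variant_kind = "insertion")
  cds <- unname(gen_cds(cfg))
  v1 <- gen_variant(cds, cfg)
  expect_identical(v1, gen_variant(cds, cfg))
  pc <- call_consequence(cds, v1)
  expect_true(pc$is_frameshift)

  snv_cfg <- sim_config(seed = 6, n_codons = 80, variant_kind = "snv")
  snv_cds <- unname(gen_cds(snv_cfg))
  snv <- gen_variant(snv_cds, snv_cfg)
  pc2 <- call_consequence(snv_cds, snv)
  expect_false(pc2$is_frameshift)
  # a silent draw is flagged, not dropped
  expect_true(is.logical(pc2$silent))

  # 500 seeded draws reproduce exactly
  for (seed in 1:50) {
    c2 <- sim_config(seed = seed, n_codons = 40)
    cd <- unname(gen_cds(c2))
    draws1 <- replicate(10, format_coding_hgvs(gen_variant(cd, c2)))
    expect_equal(length(unique(draws1)), 1L)
  }
})

test_that("synthetic strong-binder fractions match the log-normal law", {
  # 2,500 windows x 4 alleles = 10,000 mutant records
  pairs <- tibble::tibble(
    start = 1:2500, k = 9,
    wt_peptide = sprintf("WTPEP%04d", 1:2500),
    mut_peptide = sprintf("MUTPE%04d", 1:2500),
    n_altered = 1L, wt_truncated = FALSE
  )
  alleles <- c("A*02:01", "B*35:01", "C*03:03", "A*11:01")
  cfg <- sim_config(seed = 12, n_codons = 100)
  tbl <- gen_score_table(pairs, alleles, cfg)
  expect_identical(tbl, gen_score_table(pairs, alleles, cfg))

  is_mut <- grepl("^MUTPE", tbl$peptide)
  expect_equal(sum(is_mut), 10000L)
  frac_strong <- mean(tbl$affinity_nm[is_mut] <= 500)
  expected <- pnorm((log10(500) - cfg$mut_affinity_log10_mean) /
                      cfg$mut_affinity_log10_sd)
  expect_lt(abs(frac_strong - expected), 0.03)

  # wildtype mixture: with p_wt_strong = 0 essentially no strong wildtypes
  cfg0 <- sim_config(seed = 13, p_wt_strong = 0)
  tbl0 <- gen_score_table(pairs, alleles, cfg0)
  wt0 <- tbl0$affinity_nm[grepl("^WTPEP", tbl0$peptide)]
  expect_equal(length(wt0), 10000L)
  expect_lte(mean(wt0 <= 500), 0.01)
})

test_that("the simulated pipeline equals a brute-force filter end to end", {
  n_checked <- 0
  for (seed in 1:12) {
    cfg <- sim_config(seed = seed, n_codons = 80, variant_kind = "insertion")
    run <- simulate_run(cfg)
    expect_true(run$consequence$is_frameshift)
    if (!nrow(run$pairs)) {
      # the shifted frame opened directly on a stop: no novel residues
      expect_equal(run$consequence$alt_aa, "Ter")
      expect_null(run$candidates)
      next
    }
    want <- oracle_filter(run$scored,
                          max_nm = 500, need_tcr = TRUE, min_ratio = 0)
    got <- run$candidates
    expect_equal(nrow(got), nrow(want))
    expect_setequal(
      paste(got$mut_peptide, got$allele),
      paste(want$mut_peptide, want$allele))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
})

test_that("a simulated run directory is reproducible byte for byte", {
  cfg <- sim_config(seed = 7, n_codons = 60, variant_kind = "insertion")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_run(cfg, dir = d1)
  simulate_run(cfg, dir = d2)
  files <- list.files(d1)
  expect_setequal(files, c("cds.fasta", "variant.tsv", "pairs.tsv",
                           "scores.tsv", "report.json", "config.yaml"))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_codons = 10), "at least 20")
  expect_error(sim_config(p_wt_strong = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(mut_affinity_log10_sd = 0), "positive")
})
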