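test_that("variant application edits the CDS with length bookkeeping", {
  cds <- "ATGTCTGGATAA"
  ins <- apply_variant(cds, parse_coding_hgvs("c.4_5insT"))
  expect_equal(nchar(ins), nchar(cds) + 1)
  expect_equal(substr(ins, 5, 5), "T")

  fx <- apc_example()
  mut <- apply_variant(fx$wt_cds, fx$variant)
  expect_equal(nchar(mut), nchar(fx$wt_cds) + 1)

  # an SNV followed by its inverse restores the input
  snv <- coding_variant("snv", 5, ref_seq = "C", alt_seq = "G")
  inv <- coding_variant("snv", 5, ref_seq = "G", alt_seq = "C")
  expect_identical(apply_variant(apply_variant(cds, snv), inv), cds)
})

test_that("reference mismatches and out-of-range variants are reported", {
  cds <- "ATGTCTGGATAA"
  expect_error(apply_variant(cds, parse_coding_hgvs("c.4A>G")),
               "expected A, observed T")
  expect_error(apply_variant(cds, parse_coding_hgvs("c.50del")), "past the CDS")
})

test_that("deleting then re-inserting the deleted bases restores the CDS", {
  set.seed(7)
  for (i in 1:500) {
    n <- 3 * sample(5:40, 1)
    cds <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    # keep at least one base after the deletion: re-insertion needs both
    # flanks to exist in the shortened sequence
    start <- sample(1:(n - 2), 1)
    end <- min(n - 1, start + sample(0:4, 1))
    del <- coding_variant("deletion", start, end)
    cut <- apply_variant(cds, del)
    removed <- substr(cds, start, end)
    restored <- if (start == 1) {
      paste0(removed, cut)
    } else {
      ins <- coding_variant("insertion", start - 1, start, alt_seq = removed)
      apply_variant(cut, ins)
    }
    expect_identical(restored, cds)
  }
})

test_that("translation follows the standard code and stops at the first stop", {
  expect_equal(as.character(translate_cds("ATGTTTTAA")), "MF")
  mk <- translate_cds("ATGAAA")
  expect_equal(as.character(mk), "MK")
  expect_true(attr(mk, "no_stop"))
  expect_false(attr(translate_cds("ATGTTTTAA"), "no_stop"))
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
  expect_error(translate_cds("TTGAAATAA", require_start = TRUE), "ATG")
  # trailing partial codon ignored
  expect_equal(as.character(translate_cds("ATGAAAGG")), "MK")
})

test_that("translation matches an independent codon-table oracle", {
  set.seed(11)
  for (i in 1:1000) {
    n <- 3 * sample(1:30, 1) + sample(0:2, 1)
    if (n < 3) n <- 3
    dna <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    expect_identical(as.character(translate_cds(dna)), oracle_translate(dna),
                     label = dna)
  }
})

test_that("the packaged insertion yields the truncating frameshift consequence", {
  fx <- apc_example()
  pc <- fx$consequence
  expect_identical(fx$phgvs, "p.Ser246PhefsTer6")
  expect_equal(pc$position, 246L)
  expect_equal(pc$ref_aa, "Ser")
  expect_equal(pc$alt_aa, "Phe")
  expect_true(pc$is_frameshift)
  expect_equal(pc$ter_offset, 6L)
  expect_equal(mutant_protein_length(pc), 250L)
  expect_equal(nchar(fx$mut_protein), 250L)
})

test_that("substitutions and silent variants are named without a frameshift", {
  cds <- "ATGTTTGGCTGGTAA" # M F G W
  # c.4T>G: TTT -> GTT, Phe2Val
  pc <- call_consequence(cds, parse_coding_hgvs("c.4T>G"))
  expect_false(pc$is_frameshift)
  expect_true(is.na(pc$ter_offset))
  expect_identical(format_protein_consequence(pc), "p.Phe2Val")
  # c.6T>C: TTT -> TTC, still Phe
  silent <- call_consequence(cds, parse_coding_hgvs("c.6T>C"))
  expect_true(silent$silent)
  expect_identical(format_protein_consequence(silent), "p.Phe2=")
  # nonsense: c.10T>T? use G>A at 10: TGG -> TGA? c.11G>A gives TGA stop
  stopv <- call_consequence(cds, parse_coding_hgvs("c.11G>A"))
  expect_identical(format_protein_consequence(stopv), "p.Trp4Ter")
})

test_that("frameshift stop offsets match a brute-force scan of the mutant", {
  set.seed(23)
  n_checked <- 0
  for (i in 1:200) {
    cfg <- sim_config(seed = 3000 + i, n_codons = sample(25:60, 1),
                      variant_kind = if (i %% 2) "insertion" else "deletion")
    cds <- unname(gen_cds(cfg))
    v <- gen_variant(cds, cfg)
    pc <- call_consequence(cds, v)
    expect_true(pc$is_frameshift)
    mut <- oracle_translate(apply_variant(cds, v))
    wt <- oracle_translate(cds)
    # brute-force: first differing residue, stop index counted from there
    j <- 1
    while (j <= min(nchar(wt), nchar(mut)) &&
           substr(wt, j, j) == substr(mut, j, j)) j <- j + 1
    if (j > nchar(mut)) next # immediate stop at the altered codon
    expect_equal(pc$position, j)
    expect_equal(pc$ter_offset, nchar(mut) + 2L - j)
    expect_equal(mutant_protein_length(pc), nchar(mut))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
})

test_that("mutant_protein_length follows position and ter offset", {
  expect_equal(
    mutant_protein_length(parse_protein_hgvs("p.Ser246PhefsTer6")), 250L)
  expect_equal(
    mutant_protein_length(parse_protein_hgvs("p.Ala2TyrfsTer2")), 2L)
  expect_error(
    mutant_protein_length(parse_protein_hgvs("p.Ala2Tyr")), "frameshift")
})

test_that("wildtype and mutant proteins share exactly the pre-shift prefix", {
  for (seed in 1:25) {
    cfg <- sim_config(seed = seed, n_codons = 40, variant_kind = "insertion")
    cds <- unname(gen_cds(cfg))
    v <- gen_variant(cds, cfg)
    pc <- call_consequence(cds, v)
    wt <- as.character(translate_cds(cds))
    mut <- as.character(attr(pc, "mut_protein"))
    p <- pc$position
    expect_identical(substr(wt, 1, p - 1), substr(mut, 1, p - 1))
    if (p <= nchar(mut) && p <= nchar(wt)) {
      expect_false(substr(wt, p, p) == substr(mut, p, p))
    }
  }
})
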