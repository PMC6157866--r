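test_that("c. notation parses into structured variants", {
  v <- parse_coding_hgvs("c.735_736insT")
  expect_s3_class(v, "coding_variant")
  expect_equal(v$kind, "insertion")
  expect_equal(v$start, 735L)
  expect_equal(v$end, 736L)
  expect_equal(v$ref_seq, "")
  expect_equal(v$alt_seq, "T")

  snv <- parse_coding_hgvs("c.1A>G")
  expect_equal(snv$kind, "snv")
  expect_equal(snv$start, 1L)
  expect_equal(snv$ref_seq, "A")
  expect_equal(snv$alt_seq, "G")

  del <- parse_coding_hgvs("c.10_12del")
  expect_equal(del$kind, "deletion")
  expect_equal(c(del$start, del$end), c(10L, 12L))

  di <- parse_coding_hgvs("c.5_6delinsAAG")
  expect_equal(di$kind, "delins")
  expect_equal(di$alt_seq, "AAG")
})

test_that("malformed c. strings fail with a named token", {
  expect_error(parse_coding_hgvs("735_736insT"), "prefix")
  expect_error(parse_coding_hgvs("c.735_736insX"), "735_736insX")
  expect_error(parse_coding_hgvs("c.735_737insT"), "adjacent")
  expect_error(parse_coding_hgvs("c.10_5del"), "end >= start")
})

test_that("formatting a parsed variant is the identity on canonical strings", {
  for (s in c("c.735_736insT", "c.1A>G", "c.10_12del", "c.10del",
              "c.5_6delinsAAG", "c.7delinsT", "c.99_100insACGT")) {
    expect_identical(format_coding_hgvs(parse_coding_hgvs(s)), s)
  }
})

test_that("random coding variants round-trip through format and parse", {
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    kind <- sample(c("snv", "insertion", "deletion", "delins"), 1)
    start <- sample(1:5000, 1)
    v <- switch(kind,
      snv = coding_variant("snv", start, ref_seq = sample(bases, 1),
                           alt_seq = sample(bases, 1)),
      insertion = coding_variant("insertion", start, start + 1,
                                 alt_seq = paste(sample(bases, sample(1:5, 1),
                                                        replace = TRUE),
                                                 collapse = "")),
      deletion = coding_variant("deletion", start, start + sample(0:5, 1)),
      delins = coding_variant("delins", start, start + sample(0:5, 1),
                              alt_seq = paste(sample(bases, sample(1:5, 1),
                                                     replace = TRUE),
                                              collapse = ""))
    )
    expect_equal(parse_coding_hgvs(format_coding_hgvs(v)), v)
  }
})

test_that("coding positions map onto codons by thirds", {
  expect_equal(coding_to_residue(736), 246L)
  expect_equal(coding_to_residue(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_error(coding_to_residue(0), "positive")

  # each consecutive triple {3r-2, 3r-1, 3r} maps to r, exhaustively
  pos <- 1:10000
  expect_equal(coding_to_residue(pos), rep(1:3334, each = 3)[pos])
  expect_true(all(diff(coding_to_residue(pos)) >= 0))
})

test_that("protein consequences format to p. notation", {
  pc <- protein_consequence("Ser", 246, "Phe", is_frameshift = TRUE,
                            ter_offset = 6)
  expect_identical(format_protein_consequence(pc), "p.Ser246PhefsTer6")
  expect_identical(
    format_protein_consequence(protein_consequence("Ala", 1, "Val")),
    "p.Ala1Val")
  expect_error(protein_consequence("Xyz", 10, "Ala"), "amino-acid")
  expect_error(protein_consequence("Ser", 246, "Phe", is_frameshift = TRUE,
                                   ter_offset = 1), "ter_offset")
})

test_that("random protein consequences round-trip through format and parse", {
  set.seed(42)
  aas <- setdiff(unname(aa_three(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])), "Ter")
  for (i in 1:1000) {
    fs <- runif(1) < 0.5
    ter <- if (fs && runif(1) < 0.8) sample(2:60, 1) else NA_integer_
    pc <- protein_consequence(sample(aas, 1), sample(1:3000, 1), sample(aas, 1),
                              is_frameshift = fs, ter_offset = ter,
                              no_stop = fs && is.na(ter))
    expect_equal(parse_protein_hgvs(format_protein_consequence(pc)), pc)
  }
})
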