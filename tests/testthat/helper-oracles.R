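# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain loops over hand-entered tables, sharing no
# code with the package internals.

# Standard genetic code, hand-entered by codon family.
ORACLE_CODE <- local({
  tab <- c(
    "TTT F", "TTC F", "TTA L", "TTG L",
    "CTT L", "CTC L", "CTA L", "CTG L",
    "ATT I", "ATC I", "ATA I", "ATG M",
    "GTT V", "GTC V", "GTA V", "GTG V",
    "TCT S", "TCC S", "TCA S", "TCG S",
    "CCT P", "CCC P", "CCA P", "CCG P",
    "ACT T", "ACC T", "ACA T", "ACG T",
    "GCT A", "GCC A", "GCA A", "GCG A",
    "TAT Y", "TAC Y", "TAA *", "TAG *",
    "CAT H", "CAC H", "CAA Q", "CAG Q",
    "AAT N", "AAC N", "AAA K", "AAG K",
    "GAT D", "GAC D", "GAA E", "GAG E",
    "TGT C", "TGC C", "TGA *", "TGG W",
    "CGT R", "CGC R", "CGA R", "CGG R",
    "AGT S", "AGC S", "AGA R", "AGG R",
    "GGT G", "GGC G", "GGA G", "GGG G"
  )
  parts <- strsplit(tab, " ", fixed = TRUE)
  setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
})

# Translate frame 1, stop at first stop, ignore trailing partial codon.
oracle_translate <- function(dna) {
  out <- character(0)
  i <- 1
  while (i + 2 <= nchar(dna)) {
    aa <- ORACLE_CODE[[substr(dna, i, i + 2)]]
    if (aa == "*") break
    out <- c(out, aa)
    i <- i + 3
  }
  paste(out, collapse = "")
}

# Brute-force enumeration of every fully-contained mutant k-mer window
# covering at least one altered residue, wildtype taken at the same start,
# duplicates collapsed to their first start.
oracle_enumerate <- function(wt, mut, k) {
  wt_v <- strsplit(wt, "")[[1]]
  mut_v <- strsplit(mut, "")[[1]]
  out <- data.frame(start = integer(), wt_peptide = character(),
                    mut_peptide = character(), n_altered = integer(),
                    wt_truncated = logical())
  if (k > length(mut_v)) return(out)
  for (s in seq_len(length(mut_v) - k + 1)) {
    idx <- s:(s + k - 1)
    mut_pep <- paste(mut_v[idx], collapse = "")
    n_alt <- 0
    for (j in idx) {
      wt_char <- if (j <= length(wt_v)) wt_v[j] else ""
      if (!identical(wt_char, mut_v[j])) n_alt <- n_alt + 1
    }
    if (n_alt >= 1) {
      wt_idx <- idx[idx <= length(wt_v)]
      out <- rbind(out, data.frame(
        start = s,
        wt_peptide = paste(wt_v[wt_idx], collapse = ""),
        mut_peptide = mut_pep,
        n_altered = n_alt,
        wt_truncated = length(wt_idx) < k
      ))
    }
  }
  out[!duplicated(out$mut_peptide), , drop = FALSE]
}

# Random protein of length n over the 20 standard residues.
random_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Random (wt, mut) instance: either an interior substitution run or a
# frameshift-style divergence (shared prefix, novel tail of random length).
random_pair_instance <- function() {
  n <- sample(20:60, 1)
  wt <- random_protein(n)
  if (runif(1) < 0.5) {
    pos <- sample(2:(n - 1), 1)
    len <- sample(1:3, 1)
    len <- min(len, n - pos + 1)
    mut <- wt
    for (j in pos:(pos + len - 1)) {
      old <- substr(mut, j, j)
      repl <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], old), 1)
      substr(mut, j, j) <- repl
    }
    list(wt = wt, mut = mut)
  } else {
    pos <- sample(2:(n - 1), 1)
    tail_len <- sample(1:25, 1)
    mut <- paste0(substr(wt, 1, pos - 1), random_protein(tail_len))
    list(wt = wt, mut = mut)
  }
}

# Brute-force prioritization filter mirroring the documented rules.
oracle_filter <- function(tbl, max_nm, need_tcr, min_ratio) {
  keep <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    ok <- !is.na(tbl$mut_affinity_nm[i]) && tbl$mut_affinity_nm[i] <= max_nm
    if (ok && need_tcr) {
      ok <- !is.na(tbl$mut_tcr_pass[i]) && tbl$mut_tcr_pass[i]
    }
    if (ok && min_ratio > 0 && !is.na(tbl$wt_affinity_nm[i])) {
      ok <- tbl$wt_affinity_nm[i] / tbl$mut_affinity_nm[i] >= min_ratio
    }
    keep[i] <- ok
  }
  tbl[keep, , drop = FALSE]
}

# Random scored table for prioritization properties.
random_scored_table <- function(n) {
  tibble::tibble(
    mut_peptide = replicate(n, random_protein(9)),
    allele = sample(c("A*02:01", "B*35:01", "C*03:03"), n, replace = TRUE),
    key = allele,
    mut_affinity_nm = 10^runif(n, 0, 4.7),
    mut_tcr_pass = sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                          prob = c(0.45, 0.45, 0.1)),
    wt_affinity_nm = ifelse(runif(n) < 0.8, 10^runif(n, 0, 4.7), NA_real_)
  )
}
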