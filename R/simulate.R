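# Seeded synthetic-data generator: coding sequences whose frameshifted
# reading frames terminate promptly, variants of each supported kind, and
# score tables with the wildtype-vs-mutant affinity contrast the analysis
# assumes (mutant peptides mostly strong binders, wildtype counterparts
# mostly weak, with a small strong-wildtype admixture). All draws are
# functions of the config seed alone; the global RNG stream is untouched.

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  STOP_CODONS
)
# Fixed pre-stop tail (Leu-Ser-Asp-stop): places stop codons in both
# shifted reading frames as late as is structurally possible, so
# frameshifts arising near the 3' end still terminate.
CDS_TAIL <- c("CTG", "AGT", "GAT", "TAA")

#' Simulation configuration
#'
#' Defaults are calibrated to the published score tables: mutant IC50s are
#' log-normal with median ~50 nM (printed mutants span 13.71-621.64 nM),
#' wildtype IC50s log-normal with median ~16,000 nM (printed wildtypes
#' mostly 13,575-28,178 nM), and with probability `p_wt_strong` (default
#' 0.125, one of the eight printed wildtype rows) a wildtype counterpart
#' is drawn from the mutant law instead.
#'
#' @param seed Integer seed driving every draw.
#' @param n_codons Total codons including start and stop (>= 20).
#' @param variant_kind `"insertion"`, `"deletion"`, `"snv"` or `"delins"`.
#' @param fs_max_extension Maximum novel residues a frameshift may run
#'   before a stop is guaranteed (default 30).
#' @param mut_affinity_log10_mean,mut_affinity_log10_sd Log10-normal law
#'   of mutant affinities in nM (defaults 1.7 / 0.5).
#' @param wt_affinity_log10_mean,wt_affinity_log10_sd Log10-normal law of
#'   wildtype affinities in nM (defaults 4.2 / 0.3).
#' @param p_wt_strong Probability a wildtype counterpart is drawn from the
#'   mutant (strong) law (default 0.125).
#' @param p_tcr_positive Probability of a passing mutant TCR call
#'   (default 0.5).
#' @param k Peptide window length (default 9).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_codons = 100L,
                       variant_kind = c("insertion", "deletion", "snv", "delins"),
                       fs_max_extension = 30L,
                       mut_affinity_log10_mean = 1.7, mut_affinity_log10_sd = 0.5,
                       wt_affinity_log10_mean = 4.2, wt_affinity_log10_sd = 0.3,
                       p_wt_strong = 0.125, p_tcr_positive = 0.5, k = 9L) {
  variant_kind <- match.arg(variant_kind)
  n_codons <- as.integer(n_codons)
  if (is.na(n_codons) || n_codons < 20L) abort("n_codons must be at least 20")
  for (p in c(p_wt_strong, p_tcr_positive)) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  }
  if (mut_affinity_log10_sd <= 0 || wt_affinity_log10_sd <= 0) {
    abort("affinity log10 sds must be positive")
  }
  structure(list(
    seed = as.integer(seed), n_codons = n_codons, variant_kind = variant_kind,
    fs_max_extension = as.integer(fs_max_extension),
    mut_affinity_log10_mean = mut_affinity_log10_mean,
    mut_affinity_log10_sd = mut_affinity_log10_sd,
    wt_affinity_log10_mean = wt_affinity_log10_mean,
    wt_affinity_log10_sd = wt_affinity_log10_sd,
    p_wt_strong = p_wt_strong, p_tcr_positive = p_tcr_positive,
    k = as.integer(k)
  ), class = "sim_config")
}

# Distance (in shifted codons, 1-based: the stop codon's own index) from a
# frameshift starting at codon i to the first stop in the shifted frame,
# or NA if the shifted frame runs out of sequence first.
shifted_stop_distance <- function(cds, codon, offset) {
  start <- 3L * (codon - 1L) + 1L + offset
  d <- 0L
  while (start + 2L <= nchar(cds)) {
    d <- d + 1L
    if (substr(cds, start, start + 2L) %in% STOP_CODONS) return(d)
    start <- start + 3L
  }
  NA_integer_
}

#' Check prompt frameshift termination of a CDS
#'
#' `TRUE` when, for both shifted reading frames (+1 and +2 nucleotide
#' offsets, covering 1-nt deletions and insertions), a frameshift starting
#' at any codon from 2 to `n_codons - 3` reaches a stop within
#' `fs_max_extension` shifted codons. Frameshifts in the final two sense
#' codons are excluded: too little sequence remains there for a shifted
#' stop to exist at all.
#'
#' @param cds CDS string.
#' @param fs_max_extension Maximum allowed distance in codons.
#' @return Logical.
#' @export
fs_termination_ok <- function(cds, fs_max_extension = 30L) {
  n_codons <- nchar(cds) %/% 3L
  for (offset in 1:2) {
    for (i in 2:(n_codons - 3L)) {
      d <- shifted_stop_distance(cds, i, offset)
      if (is.na(d) || d > fs_max_extension) return(FALSE)
    }
  }
  TRUE
}

#' Generate a coding sequence
#'
#' ATG start, a single terminal stop, no internal in-frame stop, and a
#' fixed three-codon pre-stop tail placing stops in both shifted frames
#' near the 3' end. Interior codons are drawn uniformly from the 61 sense
#' codons and the whole interior is rejection-resampled until
#' [fs_termination_ok()] holds, so any +1/-1 frameshift arising at codons
#' `2 .. n_codons - 3` terminates within `fs_max_extension` codons.
#'
#' @param cfg A [sim_config()].
#' @param max_tries Resampling budget (default 10000).
#' @return A named CDS string of `3 * n_codons` nt.
#' @examples
#' cds <- gen_cds(sim_config(seed = 1, n_codons = 60))
#' @export
gen_cds <- function(cfg, max_tries = 10000L) {
  stopifnot(inherits(cfg, "sim_config"))
  n_interior <- cfg$n_codons - 1L - length(CDS_TAIL)
  local_rng_eval(cfg$seed, function() {
    for (t in seq_len(max_tries)) {
      u <- runif(n_interior)
      codons <- SENSE_CODONS[ceiling(u * length(SENSE_CODONS))]
      cds <- paste(c("ATG", codons, CDS_TAIL), collapse = "")
      if (fs_termination_ok(cds, cfg$fs_max_extension)) {
        return(setNames(cds, paste0("sim_cds_seed", cfg$seed)))
      }
    }
    abort(paste0("no CDS satisfying frameshift termination within ",
                 cfg$fs_max_extension, " codons after ", max_tries,
                 " tries; consider a larger fs_max_extension"))
  })
}

#' Generate a coding variant on a simulated CDS
#'
#' Draws a codon uniformly over the guaranteed-termination interior
#' (codons `2 .. n_codons - 4`, so that even an insertion at the codon's
#' 3' boundary starts its shifted frame inside the guaranteed region) and
#' emits the configured kind: a 1-nt
#' insertion after the codon's last base (the published class of
#' mutation), a 1-nt deletion of its first base, an SNV at its first base,
#' or a 1-nt delins at its first base.
#'
#' @param cds A CDS string from [gen_cds()].
#' @param cfg A [sim_config()].
#' @return A [coding_variant()].
#' @export
gen_variant <- function(cds, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_codons <- nchar(cds) %/% 3L
  draws <- local_rng_draws(cfg$seed + 104729L, 2L)
  codon <- 2L + floor(draws[1] * (n_codons - 5L))
  pos <- 3L * (codon - 1L) + 1L
  base <- substr(cds, pos, pos)
  others <- setdiff(c("A", "C", "G", "T"), base)
  alt <- others[ceiling(draws[2] * 3)]
  switch(cfg$variant_kind,
    insertion = coding_variant("insertion", pos + 2L, pos + 3L, alt_seq = alt),
    deletion = coding_variant("deletion", pos, pos, ref_seq = base),
    snv = coding_variant("snv", pos, pos, ref_seq = base, alt_seq = alt),
    delins = coding_variant("delins", pos, pos, alt_seq = alt)
  )
}

#' Generate a synthetic score table for peptide pairs
#'
#' Mutant affinities are drawn from
#' `10^Normal(mut_affinity_log10_mean, mut_affinity_log10_sd)`; each
#' wildtype counterpart comes from the mutant (strong) law with
#' probability `p_wt_strong` and otherwise from the wildtype (weak) law.
#' Mutant TCR calls are Bernoulli(`p_tcr_positive`); wildtype TCR calls
#' are left unpublished-style `NA`. Fully reproducible under the config
#' seed.
#'
#' @param pairs A pairs tibble from [enumerate_pairs()].
#' @param alleles Character vector of HLA alleles to score against.
#' @param cfg A [sim_config()].
#' @return A score tibble of the [read_score_table()] shape, one mutant
#'   and (where present) one wildtype record per (pair, allele).
#' @export
gen_score_table <- function(pairs, alleles, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!nrow(pairs)) abort("gen_score_table() needs at least one pair")
  allele_tbl <- parse_hla(alleles)
  grid <- tidyr::expand_grid(pair = seq_len(nrow(pairs)),
                             allele = allele_tbl$allele)
  n <- nrow(grid)
  draws <- local_rng_draws(cfg$seed + 7919L, 4L * n)
  z_mut <- stats::qnorm(draws[seq_len(n)])
  z_wt <- stats::qnorm(draws[n + seq_len(n)])
  u_mix <- draws[2L * n + seq_len(n)]
  u_tcr <- draws[3L * n + seq_len(n)]

  mut_aff <- 10^(cfg$mut_affinity_log10_mean + cfg$mut_affinity_log10_sd * z_mut)
  wt_strong <- u_mix < cfg$p_wt_strong
  wt_aff <- ifelse(
    wt_strong,
    10^(cfg$mut_affinity_log10_mean + cfg$mut_affinity_log10_sd * z_wt),
    10^(cfg$wt_affinity_log10_mean + cfg$wt_affinity_log10_sd * z_wt)
  )
  tcr <- ifelse(u_tcr < cfg$p_tcr_positive, "Positive", "Negative")

  mut_rows <- tibble(
    peptide = pairs$mut_peptide[grid$pair],
    allele = grid$allele,
    affinity_nm = mut_aff,
    tap_score = NA_real_, processing_score = NA_real_,
    tcr_binding = tcr
  )
  has_wt <- nzchar(pairs$wt_peptide[grid$pair]) & !pairs$wt_truncated[grid$pair]
  wt_rows <- tibble(
    peptide = pairs$wt_peptide[grid$pair],
    allele = grid$allele,
    affinity_nm = wt_aff,
    tap_score = NA_real_, processing_score = NA_real_,
    tcr_binding = NA_character_
  )[has_wt, ]
  out <- dplyr::bind_rows(mut_rows, wt_rows) |>
    dplyr::distinct(.data$peptide, .data$allele, .keep_all = TRUE)
  parsed <- parse_hla(out$allele)
  out$key <- parsed$key
  out$tcr_pass <- normalize_tcr(out$tcr_binding)
  dplyr::select(out, "peptide", "allele", "key", "affinity_nm",
                "tap_score", "processing_score", "tcr_binding", "tcr_pass")
}

#' Run a fully synthetic pipeline and write a run directory
#'
#' Generates a CDS and variant, names the consequence, enumerates peptide
#' pairs, generates a score table, scores and prioritizes — then writes
#' `cds.fasta`, `variant.tsv`, `pairs.tsv`, `scores.tsv`, `report.json`
#' and `config.yaml` into `dir`. A pure function of the config.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param alleles HLA alleles to score against.
#' @param priority A [priority_config()].
#' @return A list: `cds`, `variant`, `consequence`, `pairs`, `scores`,
#'   `scored`, `candidates`, `dir`.
#' @export
simulate_run <- function(cfg, dir = NULL,
                         alleles = c("A*02:01", "B*35:01"),
                         priority = priority_config()) {
  cds <- gen_cds(cfg)
  v <- gen_variant(unname(cds), cfg)
  pc <- call_consequence(unname(cds), v)
  wt_p <- as.character(translate_cds(unname(cds)))
  mut_p <- as.character(attr(pc, "mut_protein"))
  pairs <- if (pc$silent) {
    enumerate_pairs(wt_p, wt_p, k = cfg$k) # empty: nothing altered
  } else {
    enumerate_pairs(wt_p, mut_p, k = cfg$k)
  }
  if (nrow(pairs)) {
    scores <- gen_score_table(pairs, alleles, cfg)
    scored <- score_pairs(pairs, alleles, scorer_table(scores))
    candidates <- prioritize_pairs(scored, priority)
  } else {
    scores <- scored <- candidates <- NULL
  }
  out <- list(cds = cds, variant = v, consequence = pc, pairs = pairs,
              scores = scores, scored = scored, candidates = candidates,
              dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(cds, file.path(dir, "cds.fasta"), type = "dna")
    readr::write_tsv(
      tibble(variant_id = "sim1", chgvs = format_coding_hgvs(v),
             label = NA_character_),
      file.path(dir, "variant.tsv"), progress = FALSE)
    write_pairs(pairs, file.path(dir, "pairs.tsv"))
    if (!is.null(scores)) {
      readr::write_tsv(dplyr::select(scores, -"key", -"tcr_pass"),
                       file.path(dir, "scores.tsv"), progress = FALSE)
    }
    report <- list(
      variant_id = "sim1",
      chgvs = format_coding_hgvs(v),
      phgvs = format_protein_consequence(pc),
      is_frameshift = pc$is_frameshift,
      mutant_length = nchar(mut_p),
      n_pairs = nrow(pairs),
      n_candidates = if (is.null(candidates)) 0L else nrow(candidates)
    )
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  out
}
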