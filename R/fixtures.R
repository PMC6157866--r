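# Packaged example data. The coding sequence is a SYNTHETIC 261-codon
# context constructed so that the published APC family mutation applies at
# its true coding offset: c.735_736insT produces p.Ser246PhefsTer6, a
# truncated 250-residue mutant protein, wildtype residues 238-246 spell
# QATEAERSS, and 9-mer enumeration yields exactly five wildtype/mutant
# pairs with QATEAERSF at start 238. It is not the native APC transcript
# (full-length APC is ~2843 residues); it reproduces the published local
# sequence context only. The score, HLA and cohort tables are transcribed
# from the published family study.

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/` (empty to list).
#' @return Absolute path.
#' @examples
#' neofs_extdata()
#' @export
neofs_extdata <- function(file = "") {
  out <- system.file("extdata", file, package = "neofs")
  if (!nzchar(out)) abort(paste0("no packaged file named '", file, "'"))
  out
}

#' Synthetic APC coding context
#'
#' A synthetic 261-codon coding sequence (ATG start, single terminal stop)
#' carrying the published local context of the APC family frameshift at
#' its true coding offset, so `c.735_736insT` applies directly.
#'
#' @return A single named CDS string (783 nt).
#' @examples
#' nchar(apc_synthetic_cds())
#' @export
apc_synthetic_cds <- function() {
  read_fasta(neofs_extdata("apc_cds_synthetic.fasta"))
}

#' Worked APC frameshift example
#'
#' Bundles the synthetic coding context, the family's insertion variant,
#' both translated proteins and the named consequence.
#'
#' @return A list: `wt_cds`, `variant` (a [coding_variant()]),
#'   `consequence` (a [protein_consequence()]), `wt_protein`,
#'   `mut_protein`, `phgvs`.
#' @examples
#' apc_example()$phgvs
#' @export
apc_example <- function() {
  wt_cds <- unname(apc_synthetic_cds())
  v <- parse_coding_hgvs("c.735_736insT")
  pc <- call_consequence(wt_cds, v)
  list(
    wt_cds = wt_cds,
    variant = v,
    consequence = pc,
    wt_protein = as.character(translate_cds(wt_cds)),
    mut_protein = as.character(attr(pc, "mut_protein")),
    phgvs = format_protein_consequence(pc)
  )
}

#' Transcribed family-study score table (wildtype and mutant 9-mer)
#'
#' Affinity, TAP, processing and TCR-binding records for the
#' QATEAERSS/QATEAERSF pair at B*35:01 and C*03:03.
#'
#' @return A score tibble (see [read_score_table()]).
#' @export
table3_scores <- function() read_score_table(neofs_extdata("table3_scores.tsv"))

#' Transcribed database-screen score table (six mutant peptides)
#'
#' Wildtype and mutant affinities for the six frequently observed APC
#' mutation peptides (eight peptide-allele rows); wildtype TCR calls were
#' not published and stay `NA`.
#'
#' @return A score tibble (see [read_score_table()]).
#' @export
table5_scores <- function() read_score_table(neofs_extdata("table5_scores.tsv"))

#' Database-screen mutation panel as scored pair rows
#'
#' Joins the transcribed panel (mutation labels, wildtype/mutant peptide
#' pairing per allele) with its score table into the scored-row shape that
#' [prioritize_pairs()] consumes.
#'
#' @return A tibble with one row per (mutant peptide, allele):
#'   `mut_id`, `variant`, `wt_peptide`, `mut_peptide`, `allele`, `key`,
#'   `mut_affinity_nm`, `mut_tcr`, `mut_tcr_pass`, `wt_affinity_nm`.
#' @examples
#' apc_mutation_panel()
#' @export
apc_mutation_panel <- function() {
  panel <- readr::read_tsv(neofs_extdata("table5_panel.tsv"),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  scores <- table5_scores()
  panel$key <- hla_key(panel$allele)
  mut <- dplyr::left_join(
    panel,
    dplyr::select(scores, "peptide", "key",
                  mut_affinity_nm = "affinity_nm",
                  mut_tcr = "tcr_binding", mut_tcr_pass = "tcr_pass"),
    by = c(mut_peptide = "peptide", key = "key")
  )
  out <- dplyr::left_join(
    mut,
    dplyr::select(scores, "peptide", "key", wt_affinity_nm = "affinity_nm"),
    by = c(wt_peptide = "peptide", key = "key")
  )
  dplyr::select(out, "mut_id", "variant", "wt_peptide", "mut_peptide",
                "allele", "key", "mut_affinity_nm", "mut_tcr",
                "mut_tcr_pass", "wt_affinity_nm")
}

#' Transcribed family cohort table
#'
#' @return A cohort tibble (see [read_cohort()]).
#' @export
table1_cohort <- function() read_cohort(neofs_extdata("table1_cohort.tsv"))

#' Transcribed donor HLA genotypes
#'
#' Class-I typing (loci A, B, C; four-field where published) for the three
#' typed family members IV.9, IV.2 and III.5.
#'
#' @return A long genotype tibble (see [read_hla_genotypes()]).
#' @export
table2_hla <- function() read_hla_genotypes(neofs_extdata("table2_hla.tsv"))
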