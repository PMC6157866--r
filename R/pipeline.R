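# End-to-end pipeline: variant -> consequence -> peptide pairs -> scores
# -> prioritized, optionally HLA-restricted candidates, plus an optional
# cohort summary. Deterministic given its inputs; when an output
# directory is given, each stage's artifact is written alongside a run
# manifest echoing the configuration.

#' Run the full prioritization pipeline
#'
#' Each input may be given as a path to its standard on-disk format or as
#' the in-memory object the corresponding reader returns.
#'
#' @param cds Wildtype CDS: FASTA path or a single sequence string.
#' @param variant A c.-notation string, a [coding_variant()], or a path to
#'   a variant TSV (first row used).
#' @param scores Score table: TSV path, score tibble, or a scorer function
#'   (see [scorer_table()], [scorer_mock()]).
#' @param alleles HLA alleles to score against; defaults to the alleles
#'   present in a score table, or the donor genotype's alleles.
#' @param hla Optional donor genotypes: TSV path or tibble from
#'   [read_hla_genotypes()].
#' @param donor Donor id to restrict candidates to (required when `hla`
#'   covers several donors).
#' @param cohort Optional cohort table: TSV path or tibble from
#'   [read_cohort()].
#' @param k Peptide window length (class-I convention is 8-11; a warning
#'   is issued below 8).
#' @param priority A [priority_config()].
#' @param out_dir Optional output directory for stage artifacts.
#' @return An object of class `neofs_run`: a list with `consequence`
#'   (one-row tibble), `pairs`, `scored`, `candidates`, `restricted`,
#'   `cohort_summary`, and `config`.
#' @examples
#' run <- run_pipeline(
#'   cds = apc_synthetic_cds(), variant = "c.735_736insT",
#'   scores = table3_scores(), hla = table2_hla(), donor = "IV.9",
#'   priority = family_profile())
#' glance(run)
#' @export
run_pipeline <- function(cds, variant, scores,
                         alleles = NULL, hla = NULL, donor = NULL,
                         cohort = NULL, k = 9L,
                         priority = priority_config(), out_dir = NULL) {
  k <- as.integer(k)
  if (k < 8L) warn("k below 8 is unusual for class-I presentation")

  if (is.character(cds) && length(cds) == 1L && file.exists(cds)) {
    cds <- read_fasta(cds)
  }
  if (length(cds) > 1L) cds <- cds[1]
  cds <- unname(cds)

  variant_id <- "variant1"
  if (inherits(variant, "coding_variant")) {
    v <- variant
  } else if (is.character(variant) && length(variant) == 1L) {
    if (file.exists(variant)) {
      vt <- read_variants(variant)
      variant_id <- vt$variant_id[1]
      v <- parse_coding_hgvs(vt$chgvs[1])
    } else {
      v <- parse_coding_hgvs(variant)
    }
  } else {
    abort("variant must be a coding_variant, a c.-notation string, or a TSV path")
  }

  if (is.function(scores)) {
    scorer <- scores
    score_tbl <- NULL
  } else {
    if (is.character(scores)) scores <- read_score_table(scores)
    score_tbl <- scores
    scorer <- scorer_table(scores)
  }

  genotypes <- NULL
  if (!is.null(hla)) {
    genotypes <- if (is.character(hla)) read_hla_genotypes(hla) else hla
    if (is.null(donor)) {
      donors <- unique(genotypes$donor_id)
      if (length(donors) > 1L) {
        abort("hla covers several donors; name one with `donor`")
      }
      donor <- donors
    }
    genotypes <- dplyr::filter(genotypes, .data$donor_id == donor)
    if (!nrow(genotypes)) abort(paste0("no genotype rows for donor ", donor))
  }

  if (is.null(alleles)) {
    alleles <- if (!is.null(score_tbl)) {
      unique(score_tbl$allele)
    } else if (!is.null(genotypes)) {
      unique(genotypes$allele)
    } else {
      abort("alleles must be given when scores is a scorer function and no hla is supplied")
    }
  }

  consequence <- consequence_report(variant_id, cds, v)
  pc <- call_consequence(cds, v)
  wt_p <- as.character(translate_cds(cds))
  mut_p <- as.character(attr(pc, "mut_protein"))

  pairs <- enumerate_pairs(wt_p, mut_p, k = k)
  scored <- score_pairs(pairs, alleles, scorer)
  candidates <- prioritize_pairs(scored, priority)
  restricted <- if (!is.null(genotypes)) {
    hla_restrict(candidates, genotypes)
  } else {
    NULL
  }
  cohort_summary <- NULL
  if (!is.null(cohort)) {
    if (is.character(cohort)) cohort <- read_cohort(cohort)
    cohort_summary <- summarize_cohort(cohort)
  }

  run <- structure(list(
    consequence = consequence,
    wt_protein = wt_p, mut_protein = mut_p,
    pairs = pairs, scored = scored,
    candidates = candidates, restricted = restricted,
    cohort_summary = cohort_summary,
    config = list(variant_id = variant_id,
                  chgvs = format_coding_hgvs(v), k = k,
                  donor = donor,
                  priority = unclass(priority),
                  alleles = alleles)
  ), class = "neofs_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(as.list(run$consequence), file.path(out_dir, "consequence.json"),
                       auto_unbox = FALSE, pretty = TRUE, digits = NA)
  write_pairs(run$pairs, file.path(out_dir, "pairs.tsv"))
  readr::write_tsv(run$scored, file.path(out_dir, "scored.tsv"), progress = FALSE)
  write_candidates(run$candidates, file.path(out_dir, "candidates.tsv"))
  if (!is.null(run$restricted)) {
    write_candidates(run$restricted, file.path(out_dir, "candidates_restricted.tsv"))
  }
  if (!is.null(run$cohort_summary)) {
    readr::write_tsv(run$cohort_summary, file.path(out_dir, "cohort_summary.tsv"),
                     progress = FALSE)
  }
  manifest <- list(
    tool = "neofs",
    version = as.character(utils::packageVersion("neofs")),
    config = run$config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.neofs_run <- function(x, ...) {
  cat("<neofs_run> ", x$config$chgvs, " -> ", x$consequence$phgvs, "\n", sep = "")
  cat("  pairs: ", nrow(x$pairs),
      "  candidates: ", nrow(x$candidates), sep = "")
  if (!is.null(x$restricted)) {
    cat("  donor-restricted (", x$config$donor, "): ", nrow(x$restricted), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @describeIn run_pipeline Candidate rows of a run as a tibble (the
#'   donor-restricted set when a genotype was supplied).
#' @param x A `neofs_run`.
#' @param ... Unused.
#' @method tidy neofs_run
#' @export
tidy.neofs_run <- function(x, ...) {
  out <- x$restricted %||% x$candidates
  as_tibble(out)
}

#' @describeIn run_pipeline One-row summary of a run.
#' @method glance neofs_run
#' @export
glance.neofs_run <- function(x, ...) {
  tibble(
    chgvs = x$config$chgvs,
    phgvs = x$consequence$phgvs,
    is_frameshift = x$consequence$is_frameshift,
    mutant_length = x$consequence$mutant_length,
    n_pairs = nrow(x$pairs),
    n_scored = nrow(x$scored),
    n_candidates = nrow(x$candidates),
    n_restricted = if (is.null(x$restricted)) NA_integer_ else nrow(x$restricted),
    donor = x$config$donor %||% NA_character_
  )
}
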