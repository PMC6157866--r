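# Filtering and ranking of scored peptide pairs, and restriction of
# candidates to a donor's HLA genotype. The conventional strong-binder cut
# is an IC50 of at most 500 nM (inclusive); the family-study profile used
# for the differential wildtype-vs-mutant screen relaxes the cut to
# 1000 nM and adds a wildtype/mutant affinity-ratio requirement, because
# the printed family analysis retained a 621.64 nM binder.

#' Prioritization configuration
#'
#' @param affinity_max_nm Retain candidates with mutant IC50 at or below
#'   this many nM (inclusive; default 500, the conventional strong-binder
#'   cut).
#' @param require_tcr_positive Require a passing mutant TCR-binding call
#'   (default `TRUE`).
#' @param min_wt_mut_ratio Minimum wildtype/mutant affinity ratio
#'   (agretopicity); 0 disables the filter (default). Applied only when a
#'   wildtype affinity is present.
#' @param k Window length the pairs were enumerated at (carried for
#'   reporting; default 9).
#' @return A list of class `priority_config`.
#' @export
priority_config <- function(affinity_max_nm = 500,
                            require_tcr_positive = TRUE,
                            min_wt_mut_ratio = 0,
                            k = 9L) {
  if (!is.numeric(affinity_max_nm) || affinity_max_nm <= 0) {
    abort("affinity_max_nm must be positive")
  }
  if (min_wt_mut_ratio < 0) abort("min_wt_mut_ratio must be non-negative")
  structure(list(affinity_max_nm = affinity_max_nm,
                 require_tcr_positive = isTRUE(require_tcr_positive),
                 min_wt_mut_ratio = min_wt_mut_ratio,
                 k = as.integer(k)),
            class = "priority_config")
}

#' Family-study prioritization profile
#'
#' The run profile used to reproduce the family analysis: TCR-positive
#' requirement, affinity cut at 1000 nM, and a tenfold wildtype/mutant
#' affinity differential.
#'
#' @return A [priority_config()].
#' @export
family_profile <- function() {
  priority_config(affinity_max_nm = 1000, require_tcr_positive = TRUE,
                  min_wt_mut_ratio = 10)
}

#' Classify a binding affinity as strong or weak
#'
#' Strong means IC50 at or below the threshold (the boundary is inclusive).
#'
#' @param affinity_nm Positive IC50 values in nM (vectorised).
#' @param threshold Positive threshold in nM (default 500).
#' @return Character vector of `"strong"` / `"weak"`.
#' @examples
#' classify_binder(c(151.47, 14485.65)) # "strong" "weak"
#' @export
classify_binder <- function(affinity_nm, threshold = 500) {
  if (any(affinity_nm <= 0, na.rm = TRUE) || threshold <= 0) {
    abort("affinities and threshold must be positive")
  }
  ifelse(affinity_nm <= threshold, "strong", "weak")
}

#' Filter and rank scored peptide pairs
#'
#' Keeps rows whose mutant affinity is at or below
#' `cfg$affinity_max_nm`, whose mutant TCR call passes (when required),
#' and — when `cfg$min_wt_mut_ratio > 0` and a wildtype affinity is
#' present — whose wildtype/mutant affinity ratio reaches the configured
#' minimum. Unresolved mutant records never pass. The retained set is
#' sorted by ascending mutant affinity, ties broken by (peptide, allele),
#' and ranked.
#'
#' @param scored A tibble from [score_pairs()] (or any tibble with columns
#'   `mut_peptide`, `allele`, `mut_affinity_nm`, `mut_tcr_pass` and
#'   optionally `wt_affinity_nm`).
#' @param cfg A [priority_config()].
#' @return The retained rows with `rank`, `binder_class`, `wt_mut_ratio`
#'   and `passed_filters` columns, of class `neofs_candidates`.
#' @export
prioritize_pairs <- function(scored, cfg = priority_config()) {
  stopifnot(inherits(cfg, "priority_config"))
  if (!nrow(scored)) {
    out <- dplyr::mutate(scored, rank = integer(), binder_class = character(),
                         wt_mut_ratio = double(), passed_filters = logical())
    class(out) <- c("neofs_candidates", class(out))
    attr(out, "config") <- cfg
    return(out)
  }
  if (!"wt_affinity_nm" %in% names(scored)) scored$wt_affinity_nm <- NA_real_
  out <- scored |>
    dplyr::mutate(
      wt_mut_ratio = .data$wt_affinity_nm / .data$mut_affinity_nm,
      binder_class = ifelse(is.na(.data$mut_affinity_nm), NA_character_,
                            classify_binder(.data$mut_affinity_nm, cfg$affinity_max_nm)),
      passed_filters =
        !is.na(.data$mut_affinity_nm) &
        .data$mut_affinity_nm <= cfg$affinity_max_nm &
        (!cfg$require_tcr_positive |
           (!is.na(.data$mut_tcr_pass) & .data$mut_tcr_pass)) &
        (cfg$min_wt_mut_ratio <= 0 |
           is.na(.data$wt_affinity_nm) |
           .data$wt_mut_ratio >= cfg$min_wt_mut_ratio)
    ) |>
    dplyr::filter(.data$passed_filters) |>
    dplyr::arrange(.data$mut_affinity_nm, .data$mut_peptide, .data$allele) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  class(out) <- c("neofs_candidates", class(out))
  attr(out, "config") <- cfg
  out
}

#' Restrict candidates to a donor's HLA genotype
#'
#' Keeps candidates whose allele's two-field key equals the two-field key
#' of any allele in the donor genotype. Idempotent, and commutes with
#' [prioritize_pairs()].
#'
#' @param candidates A tibble with an allele `key` column (e.g. from
#'   [score_pairs()] or [prioritize_pairs()]).
#' @param genotype A genotype tibble from [read_hla_genotypes()] or
#'   [hla_genotype()] (one donor).
#' @return The candidate rows presented by the donor's alleles, with a
#'   `donor_id` column.
#' @export
hla_restrict <- function(candidates, genotype) {
  if (!nrow(genotype) || !"key" %in% names(genotype)) {
    abort("genotype has no parsable alleles")
  }
  donors <- unique(genotype$donor_id)
  if (length(donors) > 1L) {
    abort("hla_restrict() expects a single donor's genotype")
  }
  out <- dplyr::filter(candidates, .data$key %in% genotype$key)
  out$donor_id <- if (nrow(out)) donors else character(0)
  out
}

#' @method glance neofs_candidates
#' @export
glance.neofs_candidates <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_candidates = nrow(x),
    n_peptides = dplyr::n_distinct(x$mut_peptide),
    n_alleles = dplyr::n_distinct(x$allele),
    min_affinity_nm = if (nrow(x)) min(x$mut_affinity_nm) else NA_real_,
    affinity_max_nm = cfg$affinity_max_nm,
    require_tcr_positive = cfg$require_tcr_positive,
    min_wt_mut_ratio = cfg$min_wt_mut_ratio
  )
}

#' Write / read a candidate report
#'
#' TSV schema: `rank  mut_peptide  wt_peptide  allele  mut_affinity_nm
#' wt_affinity_nm  mut_tcr  passed_filters` plus any provenance columns
#' present.
#'
#' @param candidates A `neofs_candidates` tibble.
#' @param path File path.
#' @return `read_candidates()`: the candidates tibble.
#' @export
write_candidates <- function(candidates, path) {
  readr::write_tsv(candidates, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
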