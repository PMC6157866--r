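# Genotype/phenotype tallies of a family cohort table: carriers of the
# mutation, carriers with polyps (FAP diagnosis), polyp-free carriers.

safe_min <- function(x) if (length(x)) min(x) else NA_integer_
safe_max <- function(x) if (length(x)) max(x) else NA_integer_

#' Read a family cohort table
#'
#' TSV schema mirroring a clinical family table:
#' `sample_id  age  apc_mutation  exposure  diagnosis  surgery`.
#' `apc_mutation` is `Present (Het)` / `Absent` (normalised to
#' `present_het` / `absent`); `diagnosis` is a comma-separated label set
#' (e.g. `FAP, Oral Cancer`); `surgery` is `Yes`/`No`/empty.
#'
#' @param path Path to the cohort TSV.
#' @return A tibble: `sample_id`, `age`, `mutation`, `exposure`,
#'   `diagnosis` (list column of labels), `surgery` (logical), `has_fap`.
#' @examples
#' cohort <- read_cohort(neofs_extdata("table1_cohort.tsv"))
#' @export
read_cohort <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("sample_id", "age", "apc_mutation", "exposure", "diagnosis", "surgery")
  if (!all(need %in% names(df))) {
    abort(paste0("cohort table must have columns: ", paste(need, collapse = "  ")))
  }
  mut <- dplyr::case_when(
    grepl("present", df$apc_mutation, ignore.case = TRUE) ~ "present_het",
    grepl("absent", df$apc_mutation, ignore.case = TRUE) ~ "absent",
    .default = NA_character_
  )
  if (anyNA(mut)) {
    abort(paste0("unrecognised apc_mutation value: '",
                 df$apc_mutation[which(is.na(mut))[1]], "'"))
  }
  diagnosis <- purrr::map(df$diagnosis, function(d) {
    if (is.na(d) || !nzchar(trimws(d))) return(character(0))
    trimws(strsplit(d, ",", fixed = TRUE)[[1]])
  })
  tibble(
    sample_id = df$sample_id,
    age = as.integer(df$age),
    mutation = mut,
    exposure = ifelse(is.na(df$exposure), "", df$exposure),
    diagnosis = diagnosis,
    surgery = !is.na(df$surgery) & grepl("yes", df$surgery, ignore.case = TRUE),
    has_fap = purrr::map_lgl(diagnosis, ~ "FAP" %in% .x)
  )
}

#' Summarize carrier and phenotype structure of a cohort
#'
#' Counts individuals, mutation carriers, carriers with and without a FAP
#' diagnosis, non-carriers, and affected non-carriers, plus the age range
#' of affected and unaffected carriers. The partition identities
#' `carriers == affected_carriers + unaffected_carriers` and
#' `n == carriers + noncarriers` are asserted on every run.
#'
#' @param cohort A tibble from [read_cohort()].
#' @return A one-row tibble of counts and age ranges.
#' @examples
#' summarize_cohort(read_cohort(neofs_extdata("table1_cohort.tsv")))
#' @export
summarize_cohort <- function(cohort) {
  if (anyDuplicated(cohort$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 cohort$sample_id[duplicated(cohort$sample_id)][1]))
  }
  carrier <- cohort$mutation == "present_het"
  fap <- cohort$has_fap
  out <- tibble(
    n = nrow(cohort),
    carriers = sum(carrier),
    affected_carriers = sum(carrier & fap),
    unaffected_carriers = sum(carrier & !fap),
    noncarriers = sum(!carrier),
    affected_noncarriers = sum(!carrier & fap),
    affected_carrier_age_min = safe_min(cohort$age[carrier & fap]),
    affected_carrier_age_max = safe_max(cohort$age[carrier & fap]),
    unaffected_carrier_age_min = safe_min(cohort$age[carrier & !fap]),
    unaffected_carrier_age_max = safe_max(cohort$age[carrier & !fap])
  )
  stopifnot(out$carriers == out$affected_carriers + out$unaffected_carriers,
            out$n == out$carriers + out$noncarriers)
  out
}
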