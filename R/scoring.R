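# Score attachment: per-peptide/per-HLA records of MHC binding affinity
# (IC50, nM), TAP transport score, proteasomal processing score and a
# TCR-binding call, resolved through a pluggable scorer contract. A scorer
# is any function (peptide, allele_key) -> one-row tibble or NULL (a miss).
# Two backends ship with the package: a score-table backend (the printed
# tables are the authoritative source for reproduction) and a seeded mock.

TCR_PASS_LABELS <- c("positive", "high")
TCR_FAIL_LABELS <- c("negative", "low", "none")

normalize_tcr <- function(x) {
  low <- tolower(trimws(as.character(x)))
  dplyr::case_when(
    low %in% TCR_PASS_LABELS ~ TRUE,
    low %in% TCR_FAIL_LABELS ~ FALSE,
    .default = NA
  )
}

#' Read a peptide/HLA score table
#'
#' TSV schema:
#' `peptide  allele  affinity_nm  tap_score  processing_score  tcr_binding`
#' (`tap_score`, `processing_score` and `tcr_binding` may be `NA`).
#' Allele strings are normalised to canonical form; `tcr_binding` keeps the
#' raw vocabulary (`Positive` and `High` both count as a passing call,
#' exposed as `tcr_pass`).
#'
#' @param path Path to the score TSV.
#' @return A tibble: `peptide`, `allele`, `key`, `affinity_nm`,
#'   `tap_score`, `processing_score`, `tcr_binding`, `tcr_pass`.
#' @examples
#' scores <- read_score_table(neofs_extdata("table3_scores.tsv"))
#' @export
read_score_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("peptide", "allele", "affinity_nm", "tap_score",
            "processing_score", "tcr_binding")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("score table is missing column(s) ",
                 paste(missing, collapse = ", "),
                 "; expected header: ", paste(need, collapse = "  ")))
  }
  if (!nrow(df)) {
    return(tibble(peptide = character(), allele = character(), key = character(),
                  affinity_nm = double(), tap_score = double(),
                  processing_score = double(), tcr_binding = character(),
                  tcr_pass = logical()))
  }
  aff <- suppressWarnings(as.numeric(df$affinity_nm))
  bad <- which(is.na(aff) | aff <= 0)
  if (length(bad)) {
    abort(paste0("non-positive or unparseable affinity_nm at data row ",
                 bad[1], ": '", df$affinity_nm[bad[1]], "'"))
  }
  parsed <- parse_hla(df$allele)
  tibble(
    peptide = toupper(df$peptide),
    allele = parsed$allele,
    key = parsed$key,
    affinity_nm = aff,
    tap_score = suppressWarnings(as.numeric(df$tap_score)),
    processing_score = suppressWarnings(as.numeric(df$processing_score)),
    tcr_binding = df$tcr_binding,
    tcr_pass = normalize_tcr(df$tcr_binding)
  )
}

empty_score_record <- function() {
  tibble(affinity_nm = NA_real_, tap_score = NA_real_,
         processing_score = NA_real_, tcr_binding = NA_character_,
         tcr_pass = NA)
}

#' Table-backed scorer
#'
#' Wraps a score table (as read by [read_score_table()]) into the scorer
#' contract: `resolve(peptide, allele)` looks the pair up by peptide and
#' two-field allele key and returns the record, or `NULL` on a miss.
#'
#' @param scores A score tibble from [read_score_table()] (or of the same
#'   shape).
#' @return A scorer function `(peptide, allele) -> tibble or NULL`.
#' @export
scorer_table <- function(scores) {
  scores <- dplyr::mutate(scores, .lookup = paste(.data$peptide, .data$key))
  function(peptide, allele) {
    hit <- scores[scores$.lookup == paste(toupper(peptide), hla_key(allele)), ]
    if (!nrow(hit)) return(NULL)
    dplyr::select(hit[1, ], "affinity_nm", "tap_score",
                  "processing_score", "tcr_binding", "tcr_pass")
  }
}

# Deterministic 31-bit hash of a string, for seeding per-(peptide, allele)
# mock draws; arithmetic stays in doubles well below 2^53.
hash31 <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

#' Seeded mock scorer
#'
#' A pure function of `(peptide, allele, seed)`: affinities are drawn
#' log-uniformly on `[1, 50000]` nM, TAP and processing scores uniformly on
#' `[-2, 2]` and `[0, 2]`, and the TCR call is Bernoulli. The same
#' `(peptide, allele)` always resolves to the same record under the same
#' seed; global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param p_tcr_positive Probability of a passing TCR call.
#' @return A scorer function `(peptide, allele) -> tibble`.
#' @export
scorer_mock <- function(seed = 1L, p_tcr_positive = 0.5) {
  seed <- as.integer(seed)
  function(peptide, allele) {
    key <- paste0(toupper(peptide), "|", hla_key(allele), "|", seed)
    draws <- local_rng_draws(hash31(key), 4L)
    aff <- 10^(draws[1] * log10(50000))
    tcr <- draws[4] < p_tcr_positive
    tibble(affinity_nm = aff,
           tap_score = -2 + 4 * draws[2],
           processing_score = 2 * draws[3],
           tcr_binding = ifelse(tcr, "Positive", "Negative"),
           tcr_pass = tcr)
  }
}

# Evaluate fn() under a private RNG stream without disturbing .Random.seed.
local_rng_eval <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fn()
}

# Draw n uniforms from a private RNG stream.
local_rng_draws <- function(seed, n) local_rng_eval(seed, function() runif(n))

#' Score peptide pairs against a set of HLA alleles
#'
#' Forms the Cartesian product of pairs and alleles (input order preserved)
#' and resolves the mutant peptide — and, when present, the wildtype
#' peptide — through the scorer. Misses are carried as `NA` records with a
#' `mut_resolved` / `wt_resolved` flag rather than dropped; the total miss
#' count is attached as attribute `n_misses` and reported in a warning.
#'
#' @param pairs A pairs tibble from [enumerate_pairs()].
#' @param alleles Character vector of HLA allele names.
#' @param scorer A scorer function, e.g. [scorer_table()] or [scorer_mock()].
#' @return A tibble with one row per (pair, allele): the pair columns plus
#'   `allele`, `key`, `mut_affinity_nm`, `mut_tap`, `mut_processing`,
#'   `mut_tcr`, `mut_tcr_pass`, `mut_resolved`, and the corresponding
#'   wildtype columns.
#' @export
score_pairs <- function(pairs, alleles, scorer) {
  allele_tbl <- parse_hla(alleles)
  grid <- tidyr::expand_grid(.pair = seq_len(nrow(pairs)),
                             .allele = seq_len(nrow(allele_tbl)))
  n_miss <- 0L
  rows <- purrr::pmap_dfr(grid, function(.pair, .allele) {
    p <- pairs[.pair, ]
    a <- allele_tbl[.allele, ]
    mut <- scorer(p$mut_peptide, a$allele)
    mut_resolved <- !is.null(mut)
    if (!mut_resolved) {
      mut <- empty_score_record()
      n_miss <<- n_miss + 1L
    }
    wt <- NULL
    if (!is.na(p$wt_peptide) && nzchar(p$wt_peptide) && !p$wt_truncated) {
      wt <- scorer(p$wt_peptide, a$allele)
    }
    wt_resolved <- !is.null(wt)
    if (!wt_resolved) wt <- empty_score_record()
    dplyr::bind_cols(
      dplyr::select(p, -dplyr::any_of("starts")),
      tibble(allele = a$allele, key = a$key),
      setNames(dplyr::select(mut, "affinity_nm", "tap_score",
                             "processing_score", "tcr_binding", "tcr_pass"),
               c("mut_affinity_nm", "mut_tap", "mut_processing",
                 "mut_tcr", "mut_tcr_pass")),
      tibble(mut_resolved = mut_resolved),
      setNames(dplyr::select(wt, "affinity_nm", "tap_score",
                             "processing_score", "tcr_binding", "tcr_pass"),
               c("wt_affinity_nm", "wt_tap", "wt_processing",
                 "wt_tcr", "wt_tcr_pass")),
      tibble(wt_resolved = wt_resolved)
    )
  })
  if (n_miss > 0L) {
    warn(paste0(n_miss, " (peptide, allele) lookup(s) missed by the scorer"))
  }
  attr(rows, "n_misses") <- n_miss
  rows
}
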