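# Enumeration of aligned wildtype/mutant k-mer peptide pairs spanning the
# altered residues of a mutant protein. The wildtype counterpart of each
# window is taken at the same start coordinate on the wildtype protein,
# which is the convention that pairs QATEAERSS with QATEAERSF.

#' Locate the altered residue window of a mutant protein
#'
#' Returns the first and last altered residue indices on the mutant
#' protein. The first is the first position where the sequences differ.
#' When the proteins have different lengths (frameshift truncation or
#' extension) every residue from the first difference to the mutant's end
#' is considered altered, so the last index is `nchar(mut)`; for an
#' equal-length substitution it is the last differing position.
#'
#' @param wt,mut Wildtype and mutant protein strings (one-letter codes).
#' @return Integer vector `c(first, last)`, or `NULL` when the proteins
#'   are identical.
#' @examples
#' altered_window("MKLS", "MKFS") # c(3, 3)
#' @export
altered_window <- function(wt, mut) {
  if (!nzchar(wt) || !nzchar(mut)) abort("both proteins must be non-empty")
  wt_v <- strsplit(wt, "")[[1]]
  mut_v <- strsplit(mut, "")[[1]]
  n <- min(length(wt_v), length(mut_v))
  diffs <- which(wt_v[seq_len(n)] != mut_v[seq_len(n)])
  if (length(wt_v) != length(mut_v)) {
    first <- if (length(diffs)) diffs[1L] else n + 1L
    if (first > length(mut_v)) return(NULL) # pure truncation: nothing novel on mut
    return(c(first = first, last = length(mut_v)))
  }
  if (!length(diffs)) return(NULL)
  c(first = diffs[1L], last = diffs[length(diffs)])
}

#' Enumerate wildtype/mutant k-mer peptide pairs
#'
#' Emits one pair per window start `s` with
#' `max(1, first - k + 1) <= s <= min(last, nchar(mut) - k + 1)`: every
#' k-mer fully contained in the mutant protein that covers at least one
#' altered residue. The wildtype peptide is the same-start window on the
#' wildtype protein; when that window runs past the wildtype's end the pair
#' is flagged `wt_truncated` and the clipped wildtype fragment (possibly
#' empty) is kept. Windows never extend past the mutant stop. Duplicate
#' mutant peptides arising from repetitive sequence are collapsed to their
#' first start, with all start positions retained in `starts`.
#'
#' @param wt,mut Wildtype and mutant protein strings.
#' @param k Window length in residues (class-I convention is 8-11; default 9).
#' @return A tibble with columns `start`, `k`, `wt_peptide`, `mut_peptide`,
#'   `n_altered`, `wt_truncated`, `starts` (comma-separated provenance of
#'   collapsed duplicates). Empty (with a warning) when `k > nchar(mut)`.
#' @examples
#' fx <- apc_example()
#' enumerate_pairs(fx$wt_protein, fx$mut_protein, k = 9)
#' @export
enumerate_pairs <- function(wt, mut, k = 9L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("k must be a positive window length")
  win <- altered_window(wt, mut)
  empty <- tibble(start = integer(), k = integer(),
                  wt_peptide = character(), mut_peptide = character(),
                  n_altered = integer(), wt_truncated = logical(),
                  starts = character())
  if (is.null(win)) return(empty)
  if (k > nchar(mut)) {
    warn(paste0("window length k = ", k, " exceeds the mutant protein (",
                nchar(mut), " aa); no pairs emitted"))
    return(empty)
  }
  lo <- max(1L, win[["first"]] - k + 1L)
  hi <- min(win[["last"]], nchar(mut) - k + 1L)
  if (lo > hi) return(empty)

  wt_len <- nchar(wt)
  rows <- purrr::map_dfr(seq.int(lo, hi), function(s) {
    mut_pep <- substr(mut, s, s + k - 1L)
    wt_end <- min(s + k - 1L, wt_len)
    wt_pep <- if (s <= wt_len) substr(wt, s, wt_end) else ""
    truncated <- (s + k - 1L) > wt_len
    n_alt <- sum(strsplit(mut_pep, "")[[1]] !=
                   c(strsplit(wt_pep, "")[[1]], rep("", k))[seq_len(k)])
    tibble(start = s, k = k, wt_peptide = wt_pep, mut_peptide = mut_pep,
           n_altered = as.integer(n_alt), wt_truncated = truncated)
  })
  rows <- dplyr::filter(rows, .data$n_altered >= 1L)
  # collapse duplicate mutant peptides, keeping provenance of all starts
  rows |>
    dplyr::group_by(.data$mut_peptide) |>
    dplyr::mutate(starts = paste(.data$start, collapse = ",")) |>
    dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$start) |>
    dplyr::select("start", "k", "wt_peptide", "mut_peptide",
                  "n_altered", "wt_truncated", "starts")
}

#' Read / write a peptide-pair table
#'
#' TSV schema: `start  k  wt_peptide  mut_peptide  n_altered  wt_truncated`
#' (plus the provenance column `starts`).
#'
#' @param pairs A tibble as returned by [enumerate_pairs()].
#' @param path File path.
#' @return `read_pairs()`: the pairs tibble.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    start = "i", k = "i", wt_peptide = "c", mut_peptide = "c",
    n_altered = "i", wt_truncated = "l", starts = "c"
  ), progress = FALSE)
}
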