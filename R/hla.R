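# HLA class-I allele nomenclature: parsing, canonical rendering, and
# two-field matching keys. Typing reports carry up to four fields
# (B*35:01:01:02) while binding predictions are two-field (B35:01); the
# two-field prefix is therefore the matching key.

#' Parse an HLA class-I allele name
#'
#' Accepts the common spellings `B*35:01:01:02`, `HLA-B*35:01`,
#' `HLA*B35:01`, `HLA-A11:01` and `B35:01`. The locus must be A, B or C
#' and at least two numeric fields must be present.
#'
#' @param text Character vector of allele names.
#' @return A tibble with columns `locus`, `fields` (list of character
#'   vectors), `allele` (canonical `<locus>*<f1>:<f2>[:...]`) and `key`
#'   (two-field matching key `<locus>*<f1>:<f2>`).
#' @examples
#' parse_hla(c("B*35:01:01:02", "HLA-A11:01"))
#' @export
parse_hla <- function(text) {
  purrr::map_dfr(text, function(x) {
    raw <- x
    x <- gsub("\\s", "", x)
    x <- sub("^HLA[-*]?", "", x, ignore.case = TRUE)
    m <- regmatches(x, regexec("^([ABCabc])\\*?(\\d{1,3}(?::\\d{1,3}){1,3})$", x))[[1]]
    if (!length(m)) {
      abort(paste0("cannot parse HLA allele: '", raw,
                   "' (expected e.g. B*35:01 or HLA-A11:01)"))
    }
    locus <- toupper(m[2])
    ff <- sprintf("%02d", as.integer(strsplit(m[3], ":", fixed = TRUE)[[1]]))
    tibble(
      locus = locus,
      fields = list(ff),
      allele = paste0(locus, "*", paste(ff, collapse = ":")),
      key = paste0(locus, "*", paste(ff[1:2], collapse = ":"))
    )
  })
}

#' Canonical allele string / two-field matching key
#'
#' `format_hla()` renders the canonical `<locus>*<f1>:<f2>[:...]` form;
#' `hla_key()` truncates to the two-field matching key.
#'
#' @param text Character vector of allele names in any accepted spelling.
#' @return Character vector.
#' @examples
#' hla_key("B*35:01:01:02") # "B*35:01"
#' @export
format_hla <- function(text) parse_hla(text)$allele

#' @rdname format_hla
#' @export
hla_key <- function(text) parse_hla(text)$key

#' Read donor HLA genotypes
#'
#' TSV schema: `donor_id  locus  allele1  allele2` (one row per locus,
#' up to two alleles; a second allele equal to the first, or `NA`, encodes
#' homozygosity / a missing call).
#'
#' @param path Path to the genotype TSV.
#' @return A long tibble: `donor_id`, `locus`, `allele` (canonical),
#'   `key` (two-field).
#' @export
read_hla_genotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("donor_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    abort(paste0("HLA genotype table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(df, c("allele1", "allele2"),
                              names_to = NULL, values_to = "allele_raw")
  long <- dplyr::filter(long, !is.na(.data$allele_raw), nzchar(.data$allele_raw))
  parsed <- parse_hla(long$allele_raw)
  if (!all(parsed$locus == long$locus)) {
    bad <- which(parsed$locus != long$locus)[1]
    abort(paste0("allele ", long$allele_raw[bad], " does not match stated locus ",
                 long$locus[bad]))
  }
  tibble(donor_id = long$donor_id, locus = parsed$locus,
         allele = parsed$allele, key = parsed$key) |>
    dplyr::distinct()
}

#' Assemble a donor genotype from allele strings
#'
#' @param donor_id Donor identifier.
#' @param alleles Character vector of allele names (any accepted spelling).
#' @return A tibble like [read_hla_genotypes()] for one donor.
#' @export
hla_genotype <- function(donor_id, alleles) {
  if (!length(alleles)) abort("a genotype needs at least one allele")
  p <- parse_hla(alleles)
  tibble(donor_id = donor_id, locus = p$locus, allele = p$allele, key = p$key) |>
    dplyr::distinct()
}
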