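# Amino-acid code tables. Three-letter codes are the internal currency for
# protein-level variant notation; one-letter strings are used for peptides.

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  `*` = "Ter"
)
AA_ONE <- setNames(names(AA_THREE), AA_THREE)

#' Convert between one- and three-letter amino-acid codes
#'
#' `aa_three()` maps one-letter codes (including `*` for a stop) to
#' three-letter codes; `aa_one()` is the inverse. Both are vectorised and
#' error on codes outside the 20 standard amino acids plus the stop.
#'
#' @param x Character vector of amino-acid codes.
#' @return Character vector of converted codes.
#' @examples
#' aa_three(c("S", "F"))
#' aa_one("Ter")
#' @export
aa_three <- function(x) {
  out <- unname(AA_THREE[as.character(x)])
  if (anyNA(out)) {
    abort(paste0("unknown one-letter amino-acid code: ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  out <- unname(AA_ONE[as.character(x)])
  if (anyNA(out)) {
    abort(paste0("unknown three-letter amino-acid code: ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

is_peptide <- function(x) {
  grepl("^[ARNDCQEGHILKMFPSTWYV]+$", x)
}
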