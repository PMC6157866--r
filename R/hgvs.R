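# Parsing and formatting of coding-level (c.) and protein-level (p.) variant
# descriptions, restricted to the subset needed for coding-exon work:
#   c.<pos><ref>><alt>          single-nucleotide variant
#   c.<pos>_<pos>ins<seq>       insertion between two adjacent positions
#   c.<pos>[_<pos>]del[<seq>]   deletion
#   c.<pos>[_<pos>]delins<seq>  deletion-insertion
# Coordinates are 1-based and inclusive on the coding sequence (CDS);
# genomic coordinates are never interpreted. 3'-rule normalisation of
# ambiguous repeats is not performed.

#' Construct a coding-level variant
#'
#' Builds the record that [parse_coding_hgvs()] returns, validating the
#' structural invariants of each variant kind: an insertion sits between two
#' adjacent positions (`end == start + 1`) with empty `ref_seq`; an SNV has
#' single-base `ref_seq` and `alt_seq`; a deletion has empty `alt_seq`.
#'
#' @param kind One of `"snv"`, `"insertion"`, `"deletion"`, `"delins"`.
#' @param start,end 1-based coding nucleotide positions (inclusive; for an
#'   insertion, the flanking pair).
#' @param ref_seq,alt_seq Reference / alternate nucleotide strings (possibly
#'   empty; `ref_seq` may be empty for a deletion whose bases are implied by
#'   the coordinates).
#' @return An object of class `coding_variant`.
#' @examples
#' coding_variant("insertion", 735, 736, alt_seq = "T")
#' @export
coding_variant <- function(kind, start, end = start, ref_seq = "", alt_seq = "") {
  kind <- match.arg(kind, c("snv", "insertion", "deletion", "delins"))
  start <- as.integer(start)
  end <- as.integer(end)
  ref_seq <- toupper(ref_seq)
  alt_seq <- toupper(alt_seq)
  if (is.na(start) || start < 1L) abort("variant start must be a positive position")
  if (is.na(end) || end < start) abort("variant end must satisfy end >= start")
  for (s in c(ref = ref_seq, alt = alt_seq)) {
    if (nzchar(s) && !grepl("^[ACGT]+$", s)) {
      abort(paste0("non-ACGT characters in variant sequence: ", s))
    }
  }
  switch(kind,
    snv = {
      if (end != start) abort("an SNV occupies a single position (end == start)")
      if (nchar(ref_seq) != 1L || nchar(alt_seq) != 1L) {
        abort("an SNV needs single-base ref_seq and alt_seq")
      }
    },
    insertion = {
      if (end != start + 1L) {
        abort(paste0("insertion positions must be adjacent: got ", start, "_", end))
      }
      if (nzchar(ref_seq)) abort("an insertion has empty ref_seq")
      if (!nzchar(alt_seq)) abort("an insertion needs a non-empty alt_seq")
    },
    deletion = {
      if (nzchar(alt_seq)) abort("a deletion has empty alt_seq")
      if (nzchar(ref_seq) && nchar(ref_seq) != end - start + 1L) {
        abort("deletion ref_seq length must match the coordinate span")
      }
    },
    delins = {
      if (!nzchar(alt_seq)) abort("a delins needs a non-empty alt_seq")
      if (nzchar(ref_seq) && nchar(ref_seq) != end - start + 1L) {
        abort("delins ref_seq length must match the coordinate span")
      }
    }
  )
  structure(
    list(kind = kind, start = start, end = end,
         ref_seq = ref_seq, alt_seq = alt_seq),
    class = "coding_variant"
  )
}

#' Parse a c.-notation variant string
#'
#' Supports the grammar `c.<pos><ref>><alt>` (SNV),
#' `c.<pos>_<pos>ins<seq>`, `c.<pos>[_<pos>]del[<seq>]` and
#' `c.<pos>[_<pos>]delins<seq>`. Formatting the result with
#' [format_coding_hgvs()] reproduces the canonical form.
#'
#' @param text A single c.-notation string, e.g. `"c.735_736insT"`.
#' @return A [coding_variant()].
#' @examples
#' parse_coding_hgvs("c.735_736insT")
#' parse_coding_hgvs("c.1A>G")
#' @export
parse_coding_hgvs <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    abort("parse_coding_hgvs() expects a single string")
  }
  body <- sub("^c\\.", "", text)
  if (identical(body, text)) abort(paste0("expected 'c.' prefix in: ", text))

  m <- regmatches(body, regexec("^(\\d+)([ACGTacgt])>([ACGTacgt])$", body))[[1]]
  if (length(m)) {
    return(coding_variant("snv", as.integer(m[2]),
                          ref_seq = m[3], alt_seq = m[4]))
  }
  m <- regmatches(body, regexec("^(\\d+)_(\\d+)ins([ACGTacgt]+)$", body))[[1]]
  if (length(m)) {
    return(coding_variant("insertion", as.integer(m[2]), as.integer(m[3]),
                          alt_seq = m[4]))
  }
  m <- regmatches(body, regexec("^(\\d+)(?:_(\\d+))?delins([ACGTacgt]+)$", body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    return(coding_variant("delins", start, end, alt_seq = m[4]))
  }
  m <- regmatches(body, regexec("^(\\d+)(?:_(\\d+))?del([ACGTacgt]*)$", body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    return(coding_variant("deletion", start, end, ref_seq = m[4]))
  }
  abort(paste0("cannot parse c. variant near '", body,
               "': supported forms are <pos><ref>><alt>, <pos>_<pos>ins<seq>, ",
               "<pos>[_<pos>]del[<seq>], <pos>[_<pos>]delins<seq>"))
}

#' Format a coding variant back to c. notation
#'
#' @param v A [coding_variant()].
#' @return The canonical c.-notation string.
#' @examples
#' format_coding_hgvs(coding_variant("insertion", 735, 736, alt_seq = "T"))
#' @export
format_coding_hgvs <- function(v) {
  stopifnot(inherits(v, "coding_variant"))
  span <- if (v$end > v$start) paste0(v$start, "_", v$end) else as.character(v$start)
  switch(v$kind,
    snv = paste0("c.", v$start, v$ref_seq, ">", v$alt_seq),
    insertion = paste0("c.", v$start, "_", v$end, "ins", v$alt_seq),
    deletion = paste0("c.", span, "del", v$ref_seq),
    delins = paste0("c.", span, "delins", v$alt_seq)
  )
}

#' @export
print.coding_variant <- function(x, ...) {
  cat("<coding_variant> ", format_coding_hgvs(x), "  (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' @method tidy coding_variant
#' @export
tidy.coding_variant <- function(x, ...) {
  tibble(kind = x$kind, start = x$start, end = x$end,
         ref_seq = x$ref_seq, alt_seq = x$alt_seq,
         chgvs = format_coding_hgvs(x))
}

#' Map a coding nucleotide position to its residue index
#'
#' Codon `r` covers coding positions `3r - 2 .. 3r`, so the residue index of
#' a coding position is `ceiling(pos / 3)`.
#'
#' @param cds_pos Vector of 1-based coding nucleotide positions.
#' @return Integer vector of 1-based residue indices.
#' @examples
#' coding_to_residue(736) # codon 246
#' @export
coding_to_residue <- function(cds_pos) {
  cds_pos <- as.numeric(cds_pos)
  if (any(is.na(cds_pos)) || any(cds_pos < 1)) {
    abort("coding positions must be positive")
  }
  as.integer(ceiling(cds_pos / 3))
}

#' Construct a protein-level consequence
#'
#' The record behind p.-notation strings such as `p.Ser246PhefsTer6`: the
#' first altered residue (`ref_aa`, `position`, `alt_aa`, three-letter
#' codes), whether the change shifts the reading frame, and for truncating
#' changes the `ter_offset` — the 1-based position of the new stop counted
#' from the first altered residue (the stop codon itself carries the Ter
#' index, so `Ter6` means five novel residues then a stop).
#'
#' @param ref_aa,alt_aa Three-letter amino-acid codes.
#' @param position 1-based residue index of the first altered residue.
#' @param is_frameshift Logical.
#' @param ter_offset Positive integer or `NA` (absent for non-truncating
#'   changes). When present with a frameshift it must be >= 2: the first
#'   altered residue is itself a substituted amino acid, not a stop.
#' @param silent Logical; `TRUE` when the protein is unchanged.
#' @param no_stop Logical; `TRUE` when the shifted frame never reaches a
#'   stop within the sequence.
#' @return An object of class `protein_consequence`.
#' @examples
#' protein_consequence("Ser", 246, "Phe", is_frameshift = TRUE, ter_offset = 6)
#' @export
protein_consequence <- function(ref_aa, position, alt_aa,
                                is_frameshift = FALSE, ter_offset = NA_integer_,
                                silent = FALSE, no_stop = FALSE) {
  if (!ref_aa %in% AA_THREE || !alt_aa %in% AA_THREE) {
    abort(paste0("unknown amino-acid code: ", ref_aa, " / ", alt_aa))
  }
  position <- as.integer(position)
  if (is.na(position) || position < 1L) abort("residue position must be positive")
  ter_offset <- as.integer(ter_offset)
  if (!is.na(ter_offset)) {
    if (ter_offset < 1L) abort("ter_offset must be positive")
    if (is_frameshift && ter_offset < 2L) {
      abort("a frameshift ter_offset must be >= 2 (first altered residue is not the stop)")
    }
  }
  structure(
    list(ref_aa = ref_aa, position = position, alt_aa = alt_aa,
         is_frameshift = isTRUE(is_frameshift), ter_offset = ter_offset,
         silent = isTRUE(silent), no_stop = isTRUE(no_stop)),
    class = "protein_consequence"
  )
}

#' Format a protein consequence as a p.-notation string
#'
#' A frameshift with a known stop renders as `p.<Ref><Pos><Alt>fsTer<N>`;
#' a frameshift that never reaches a stop as `p.<Ref><Pos><Alt>fs`; a plain
#' substitution as `p.<Ref><Pos><Alt>`; a silent change as `p.<Ref><Pos>=`.
#'
#' @param pc A [protein_consequence()].
#' @return The p.-notation string.
#' @examples
#' format_protein_consequence(
#'   protein_consequence("Ser", 246, "Phe", is_frameshift = TRUE, ter_offset = 6))
#' @export
format_protein_consequence <- function(pc) {
  stopifnot(inherits(pc, "protein_consequence"))
  if (pc$silent) return(paste0("p.", pc$ref_aa, pc$position, "="))
  if (pc$alt_aa == "Ter") return(paste0("p.", pc$ref_aa, pc$position, "Ter"))
  out <- paste0("p.", pc$ref_aa, pc$position, pc$alt_aa)
  if (pc$is_frameshift) {
    out <- paste0(out, "fs")
    if (!is.na(pc$ter_offset)) out <- paste0(out, "Ter", pc$ter_offset)
  } else if (!is.na(pc$ter_offset) && pc$alt_aa != "Ter") {
    out <- paste0(out, "Ter", pc$ter_offset)
  }
  out
}

#' Parse a p.-notation consequence string
#'
#' Inverse of [format_protein_consequence()] on the supported grammar.
#'
#' @param text A p.-notation string, e.g. `"p.Ser246PhefsTer6"`.
#' @return A [protein_consequence()].
#' @export
parse_protein_hgvs <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    abort("parse_protein_hgvs() expects a single string")
  }
  body <- sub("^p\\.", "", text)
  if (identical(body, text)) abort(paste0("expected 'p.' prefix in: ", text))
  m <- regmatches(body, regexec("^([A-Z][a-z]{2})(\\d+)=$", body))[[1]]
  if (length(m)) {
    return(protein_consequence(m[2], as.integer(m[3]), m[2], silent = TRUE))
  }
  m <- regmatches(
    body,
    regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})(fs)?(?:Ter(\\d+))?$", body)
  )[[1]]
  if (!length(m)) abort(paste0("cannot parse p. consequence near '", body, "'"))
  fs <- nzchar(m[5])
  ter <- if (nzchar(m[6])) as.integer(m[6]) else NA_integer_
  protein_consequence(m[2], as.integer(m[3]), m[4],
                      is_frameshift = fs, ter_offset = ter,
                      no_stop = fs && is.na(ter))
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("<protein_consequence> ", format_protein_consequence(x), sep = "")
  if (x$silent) cat("  (silent)")
  if (x$no_stop) cat("  (no stop reached)")
  cat("\n")
  invisible(x)
}

#' @method tidy protein_consequence
#' @export
tidy.protein_consequence <- function(x, ...) {
  tibble(ref_aa = x$ref_aa, position = x$position, alt_aa = x$alt_aa,
         is_frameshift = x$is_frameshift, ter_offset = x$ter_offset,
         silent = x$silent, no_stop = x$no_stop,
         phgvs = format_protein_consequence(x))
}

#' Read a variant table
#'
#' Reads a TSV with columns `variant_id`, `chgvs` and optionally `label`,
#' parsing each c.-notation string.
#'
#' @param path Path to a tab-separated variant table.
#' @return A tibble with one row per variant: `variant_id`, `chgvs`,
#'   `label`, `kind`, `start`, `end`, `ref_seq`, `alt_seq`.
#' @export
read_variants <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("variant_id", "chgvs")
  if (!all(need %in% names(df))) {
    abort(paste0("variant table must have columns: ", paste(need, collapse = ", ")))
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  parsed <- purrr::map(df$chgvs, parse_coding_hgvs)
  dplyr::bind_cols(
    dplyr::select(df, "variant_id", "chgvs", "label"),
    purrr::map_dfr(parsed, function(v) {
      tibble(kind = v$kind, start = v$start, end = v$end,
             ref_seq = v$ref_seq, alt_seq = v$alt_seq)
    })
  )
}
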