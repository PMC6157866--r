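# Applying a coding variant to a CDS, translating, and naming the
# protein-level consequence. Sequences are plain upper-case character
# strings; FASTA I/O goes through Biostrings.

check_cds <- function(cds) {
  if (length(cds) != 1L || !is.character(cds)) abort("cds must be a single string")
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds)) abort("cds contains non-ACGT characters")
  if (nchar(cds) < 3L) abort("cds must be at least one codon long")
  cds
}

#' Read / write coding or protein sequences as FASTA
#'
#' Thin wrappers over Biostrings readers and writers returning named
#' character vectors; records are line-wrapped at 60 characters on output.
#'
#' @param path FASTA file path.
#' @param x Named character vector of sequences.
#' @param type `"dna"` or `"protein"` (write only).
#' @return `read_fasta()`: a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  ss <- if (type == "dna") Biostrings::DNAStringSet(x) else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Apply a coding variant to a coding sequence
#'
#' Edits the CDS at the variant's 1-based coding coordinates. For SNVs,
#' deletions and delins with a stated `ref_seq`, the reference bases are
#' checked against the sequence and a mismatch is an error reporting
#' expected vs observed. The output length changes by
#' `nchar(alt_seq) - nchar(ref span)`.
#'
#' @param cds Coding sequence (single ACGT string).
#' @param v A [coding_variant()].
#' @return The edited coding sequence string.
#' @examples
#' apply_variant("ATGTCTTAA", parse_coding_hgvs("c.4_5insT"))
#' @export
apply_variant <- function(cds, v) {
  cds <- check_cds(cds)
  stopifnot(inherits(v, "coding_variant"))
  n <- nchar(cds)
  if (v$end > n) {
    abort(paste0("variant ", format_coding_hgvs(v), " runs past the CDS (length ", n, ")"))
  }
  if (v$kind == "insertion") {
    return(paste0(substr(cds, 1L, v$start), v$alt_seq, substr(cds, v$start + 1L, n)))
  }
  observed <- substr(cds, v$start, v$end)
  if (v$kind == "snv" || nzchar(v$ref_seq)) {
    if (!identical(observed, v$ref_seq)) {
      abort(paste0("reference mismatch at c.", v$start,
                   ifelse(v$end > v$start, paste0("_", v$end), ""),
                   ": expected ", v$ref_seq, ", observed ", observed))
    }
  }
  paste0(substr(cds, 1L, v$start - 1L), v$alt_seq, substr(cds, v$end + 1L, n))
}

#' Translate a coding sequence
#'
#' Translates frame 1 with the standard nuclear genetic code, stopping at
#' the first stop codon; any trailing partial codon is ignored and the stop
#' symbol is excluded from the output. When no stop codon is reached the
#' full translation is returned with attribute `no_stop = TRUE`.
#'
#' @param cds Coding sequence (single ACGT string, length >= 3).
#' @param require_start If `TRUE`, error unless the first codon is ATG.
#' @return One-letter protein string; attribute `no_stop` is `TRUE` when no
#'   stop codon terminated the translation.
#' @examples
#' translate_cds("ATGTTTTAA") # "MF"
#' @export
translate_cds <- function(cds, require_start = FALSE) {
  cds <- check_cds(cds)
  if (require_start && substr(cds, 1L, 3L) != "ATG") {
    abort(paste0("first codon is ", substr(cds, 1, 3), ", not ATG"))
  }
  n_codon <- nchar(cds) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, 3L * n_codon)),
    genetic.code = Biostrings::GENETIC_CODE, no.init.codon = TRUE
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    structure(substr(aa, 1L, stop_at - 1L), no_stop = FALSE)
  } else {
    structure(aa, no_stop = TRUE)
  }
}

#' Name the protein-level consequence of a coding variant
#'
#' Translates the wildtype and mutant CDS and compares them: the result
#' records the first differing residue, whether the variant shifts the
#' reading frame (indel length not divisible by 3), and for truncating
#' changes the offset of the new stop. A variant whose protein is identical
#' to wildtype yields a consequence flagged `silent` rather than an error,
#' so pipelines can drop it downstream.
#'
#' @param wt_cds Wildtype coding sequence string.
#' @param v A [coding_variant()].
#' @return A [protein_consequence()] with attribute `mut_protein`, the
#'   translated mutant protein.
#' @examples
#' pc <- call_consequence(apc_synthetic_cds(), parse_coding_hgvs("c.735_736insT"))
#' format_protein_consequence(pc) # "p.Ser246PhefsTer6"
#' @export
call_consequence <- function(wt_cds, v) {
  wt_cds <- check_cds(wt_cds)
  mut_cds <- apply_variant(wt_cds, v)
  wt <- translate_cds(wt_cds)
  mut <- translate_cds(mut_cds)
  shift <- (nchar(v$alt_seq) - ifelse(v$kind == "insertion", 0L,
                                      v$end - v$start + 1L)) %% 3L
  is_fs <- shift != 0L

  wt_v <- strsplit(wt, "")[[1]]
  mut_v <- strsplit(mut, "")[[1]]
  n <- min(length(wt_v), length(mut_v))
  diffs <- if (n > 0L) which(wt_v[seq_len(n)] != mut_v[seq_len(n)]) else integer()

  if (!length(diffs) && length(wt_v) == length(mut_v)) {
    pos <- coding_to_residue(v$start)
    pos <- min(pos, length(wt_v))
    aa <- aa_three(wt_v[pos])
    pc <- protein_consequence(aa, pos, aa, silent = TRUE)
    attr(pc, "mut_protein") <- mut
    return(pc)
  }

  first <- if (length(diffs)) diffs[1L] else n + 1L
  no_stop <- isTRUE(attr(mut, "no_stop"))

  if (first > length(mut_v)) {
    # mutant is a proper prefix of wildtype: the first altered codon is a
    # stop, so the change is fully described as a nonsense substitution
    pc <- protein_consequence(aa_three(wt_v[first]), first, "Ter",
                              is_frameshift = is_fs, no_stop = FALSE)
    attr(pc, "mut_protein") <- mut
    return(pc)
  }

  ref_aa <- if (first <= length(wt_v)) aa_three(wt_v[first]) else "Ter"
  alt_aa <- aa_three(mut_v[first])
  ter <- NA_integer_
  if (is_fs && !no_stop) {
    # stop codon sits immediately after the mutant protein; Ter index is
    # counted from the first altered residue
    ter <- length(mut_v) + 2L - first
  }
  pc <- protein_consequence(ref_aa, first, alt_aa,
                            is_frameshift = is_fs, ter_offset = ter,
                            no_stop = is_fs && no_stop)
  attr(pc, "mut_protein") <- mut
  pc
}

#' Length of the truncated mutant protein implied by a frameshift
#'
#' Residues `1 .. position - 1` are wildtype, residues
#' `position .. position + ter_offset - 2` are novel, and the stop sits at
#' `position + ter_offset - 1`, so the mutant protein has
#' `position + ter_offset - 2` residues.
#'
#' @param pc A frameshift [protein_consequence()] with a `ter_offset`.
#' @return Integer residue count.
#' @examples
#' mutant_protein_length(parse_protein_hgvs("p.Ser246PhefsTer6")) # 250
#' @export
mutant_protein_length <- function(pc) {
  stopifnot(inherits(pc, "protein_consequence"))
  if (!pc$is_frameshift || is.na(pc$ter_offset)) {
    abort("mutant_protein_length() needs a frameshift consequence with a ter_offset")
  }
  pc$position + pc$ter_offset - 2L
}

#' One-row consequence report
#'
#' @param variant_id Identifier carried into the report.
#' @param wt_cds Wildtype CDS string.
#' @param v A [coding_variant()].
#' @return A tibble: `variant_id`, `chgvs`, `phgvs`, `is_frameshift`,
#'   `position`, `ter_offset`, `mutant_length`, `silent`.
#' @export
consequence_report <- function(variant_id, wt_cds, v) {
  pc <- call_consequence(wt_cds, v)
  tibble(
    variant_id = variant_id,
    chgvs = format_coding_hgvs(v),
    phgvs = format_protein_consequence(pc),
    is_frameshift = pc$is_frameshift,
    position = pc$position,
    ter_offset = pc$ter_offset,
    mutant_length = nchar(attr(pc, "mut_protein")),
    silent = pc$silent
  )
}
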