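# ggplot2 views of scored and prioritized peptide pairs.

#' Plot prioritized candidates
#'
#' Wildtype vs mutant IC50 on log10 axes, one point per (peptide, allele),
#' with the strong-binder threshold drawn on the mutant axis. Points on or
#' left of the vertical line are strong mutant binders; points far above
#' the diagonal bind much more weakly in wildtype form (high
#' agretopicity).
#'
#' @param object A `neofs_candidates` tibble from [prioritize_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neofs_candidates
#' @export
autoplot.neofs_candidates <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mut_affinity_nm,
                                   y = .data$wt_affinity_nm,
                                   label = .data$mut_peptide)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_vline(xintercept = cfg$affinity_max_nm,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$allele), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "mutant IC50 (nM)", y = "wildtype IC50 (nM)", colour = "HLA",
      title = "Prioritized neoepitope candidates",
      subtitle = paste0("strong-binder cut at ", cfg$affinity_max_nm, " nM")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run
#'
#' Mutant affinities of all scored windows by allele, candidates
#' highlighted.
#'
#' @param object A `neofs_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neofs_run
#' @export
autoplot.neofs_run <- function(object, ...) {
  scored <- dplyr::mutate(
    object$scored,
    retained = paste(.data$mut_peptide, .data$allele) %in%
      paste(object$candidates$mut_peptide, object$candidates$allele)
  )
  cfg <- attr(object$candidates, "config")
  ggplot2::ggplot(
    dplyr::filter(scored, !is.na(.data$mut_affinity_nm)),
    ggplot2::aes(x = factor(.data$start), y = .data$mut_affinity_nm,
                 colour = .data$allele, shape = .data$retained)
  ) +
    ggplot2::geom_hline(yintercept = cfg$affinity_max_nm,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window start (mutant residue)",
                  y = "mutant IC50 (nM)", colour = "HLA",
                  shape = "retained",
                  title = paste0(object$config$chgvs, "  ",
                                 object$consequence$phgvs)) +
    ggplot2::theme_minimal()
}
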