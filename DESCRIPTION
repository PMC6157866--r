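Package: neofs
Title: Frameshift Neoepitope Enumeration and Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing a coding-level mutation to prioritized
    neoepitope candidates. Parses HGVS-style coding and protein variant
    notation, applies variants to a coding sequence, translates and names
    the protein-level consequence (including frameshift truncations),
    enumerates aligned wildtype/mutant k-mer peptide pairs spanning the
    altered residues, attaches per-peptide/per-HLA binding, TAP,
    processing and TCR-binding scores through a pluggable scorer
    contract, filters and ranks candidates under configurable
    strong-binder thresholds, restricts candidates to a donor's HLA
    genotype, and tallies carrier/phenotype structure of a family
    cohort. A seeded synthetic-data generator produces coding sequences,
    variants and score tables with the statistical structure the
    analysis assumes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
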