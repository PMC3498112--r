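Package: lactomir
Title: Two-Library Small RNA Sequencing Analysis of the Lactating
    Mammary Gland miRNA Repertoire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested re-implementation of a classic two-library small
    RNA sequencing workflow for microRNA profiling: raw read cleaning and
    tag collapsing, genome mapping with priority-rule annotation,
    hairpin-based novel miRNA discovery under MIREAP-style structural
    criteria with a built-in RNA folding engine and dinucleotide-shuffle
    randomization test, Audic-Claverie count-based differential
    expression with reads-per-million normalization and zero-substitution
    rules, rule-based miRNA target prediction on transcript sequences,
    and hypergeometric GO/KEGG term enrichment.  A synthetic-data module
    plants hairpin precursors and decoy loci in a toy genome and
    simulates adapter-ligated libraries with a machine-readable truth
    manifest, so the whole pipeline is testable end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
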