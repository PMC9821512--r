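Package: hubseeker
Title: Common Hub Discovery in Disease Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative network-proteomics toolkit for identifying
    intermediate hub proteins shared across disease-associated protein sets.
    Implements quantitative proteomics filters (minimum peptide evidence,
    replicate presence) and ranked fold-change summaries; cutoff-free gene-set
    enrichment with a weighted running-sum statistic, gene-label permutation
    p-values and an enrichment-map overlap graph; seed-based subnetwork
    expansion on a reference interactome with degree/betweenness ranking,
    six-way subnetwork combination, common-hub calling and an empirical
    specificity null built from random seed resampling; and multi-omic
    integration calls (RNA/protein sign concordance, bivalent-chromatin and
    responsive-gene thresholds, hypergeometric overlap tests). A synthetic-data
    module generates every input with planted ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
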