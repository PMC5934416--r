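Package: ctscreen
Title: Hit Calling and Quantification for RT-qPCR-Based shRNA Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for arrayed and pooled shRNA screens that use
    RT-qPCR cycle-threshold (ct) readouts of endogenous, cytokine-inducible
    genes. Implements delta-ct normalization to a housekeeping gene, the
    2^-ddCt relative-quantification method with three knockdown comparisons
    (basal, stimulated, and stimulus-mediated regulation), Z-score ranking,
    and concordance-based hit calling across independent screens with
    coactivator/corepressor direction labels. Includes a synthetic ct-table
    generator with implanted ground-truth effects for benchmarking, a
    validation-stage fold-change classifier with overlap summaries and
    rank-sum testing, ChIP-qPCR percent-of-input quantification, and a
    permutation test for protein-interaction-network edge enrichment of a
    gene set.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
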