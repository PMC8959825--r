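Package: coexreg
Title: Weighted Co-Expression Modules, Motif Scanning and Regulatory
    Network Assembly for Stress Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stress-associated gene co-expression modules from
    expression matrices (soft-thresholded correlation adjacency, topological
    overlap, average-linkage clustering, module eigengenes and module-trait
    correlation), scans promoters for degenerate IUPAC consensus motifs with
    a mismatch budget on both strands, assembles a focal transcription-factor
    regulatory network from co-expression partners and promoter site counts,
    estimates synonymous divergence (Nei-Gojobori 1986 with Jukes-Cantor
    correction) for duplicate gene pairs and bins them into whole-genome
    duplication epochs, applies a consensus differential-expression rule over
    per-method result tables, and quantifies qPCR experiments by the
    2^-ddCt method.  A seeded synthetic-data generator plants known modules,
    promoter sites, divergence times and fold changes so every stage can be
    validated against ground truth.
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
    glue,
    igraph,
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
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
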