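Package: caflineage
Title: Discovery of Lineage-Specific Cancer-Associated Fibroblast Subtypes
    Across Single-Cell Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a multi-sample single-cell
    RNA-seq workflow for discovering a lineage-specific cancer-associated
    fibroblast (CAF) subtype and assessing its clinical relevance. Provides
    per-sample quality control, log-normalization, variable-feature
    selection and graph clustering; reference-correlation cell typing with
    a marker-gated fibroblast rule; harmonization of per-sample CAF
    subclusters via canonical correlation analysis; robust marker discovery
    by cross-sample intersection of differentially expressed genes;
    pseudotime-correlated lineage-gene selection; permutation-based
    ligand-receptor cross-talk scoring with cross-sample aggregation;
    preranked gene-set enrichment; and bulk-cohort signature scoring with
    log-rank and Cox proportional-hazards survival analysis. A seeded
    synthetic-data generator emulates the multi-sample study design so the
    whole pipeline is testable end-to-end without external downloads.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
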