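Package: immrep
Title: B-Cell Receptor Heavy-Chain Repertoire Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of adaptive immune receptor repertoire (AIRR)
    rearrangement tables for B-cell receptor heavy chains: quality
    filtering with a fixed UMI-depth threshold, rarefaction-based
    clonality and diversity indices (Gini, Shannon), clonotype clustering
    by V/J gene, CDR3 length and normalized CDR3 substitution distance,
    clonal network export, germline gene-usage matrices, somatic
    hypermutation and N-glycosylation sequon profiling, isotype
    composition, non-parametric between-group testing with multiple
    testing correction, and a gene-usage logistic classifier with ROC
    evaluation. Includes a cohort simulator that emits annotated AIRR
    tables with a ground-truth ledger for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    igraph,
    readr,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
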