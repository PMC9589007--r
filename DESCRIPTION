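Package: protflow
Title: Differential Abundance and Consensus Enrichment for Multi-Tissue Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end downstream analysis of label-free protein intensity
    matrices across multiple tissues: sample outlier exclusion, presence
    filtering, gene-level aggregation, median-sweep normalization,
    left-censored (QRILC) imputation, covariate selection by explained
    variance, empirical-Bayes moderated linear models with pi-value ranking,
    and dual pre-ranked gene-set enrichment (competitive parametric test and
    permutation GSEA) with a same-direction consensus rule, hypergeometric
    over-representation, and enrichment-map graph construction. Includes a
    synthetic-cohort generator with planted effects, covariate structure and
    missing-not-at-random censoring for power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
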