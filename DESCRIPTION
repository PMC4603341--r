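Package: panCIMP
Title: Pan-Cancer CpG Island Methylator Phenotype Calling and Integrative Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls the CpG island methylator phenotype (CIMP) from Illumina
    450K-style beta values: aggregates probe-level methylation to CpG islands
    (including shores and shelves), derives per-tissue CIMP signatures from the
    most variant islands, clusters samples with Ward linkage and assesses the
    number of CIMP classes by Monti consensus clustering with the Delta(K)
    criterion. Intersects signatures across cancer types against an analytic
    random-subset null, predicts CIMP status from gene expression with lasso,
    combined-lasso and multi-task group-lasso logistic regression (FISTA
    solver) including repeated cross-validation and bootstrap signature
    stability, tests per-gene mutation association (hypergeometric with
    Benjamini-Hochberg correction) and mutation burden, and relates CIMP to
    survival (Kaplan-Meier, log-rank, Cox) and clinical covariates. A seeded
    synthetic-data generator with planted CIMP structure provides ground truth
    for every stage, and a configurable pipeline runs them end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
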