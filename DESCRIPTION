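Package: scTypeTree
Title: Hierarchical Probability-Calibrated Cell-Type Classification for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates cells in single-cell RNA-seq expression matrices
    using a forest of binary, probability-calibrated linear classifiers,
    one per cell type. Classifiers are organised in a parent/child tree:
    a subtype model is applied only to cells accepted by its parent, so
    labels are refined along the lineage. Each cell receives a calibrated
    probability per evaluated cell type; cells passing several branches
    get an ambiguous slash-joined assignment, and cells passing none are
    rejected as "unknown", which makes populations absent from the
    reference detectable. Includes a versioned on-disk classifier
    database format, evaluation metrics (dataset-level accuracy,
    per-type and mean sensitivity/specificity, unknown population
    detection rate, with strict and intermediate-accepted scoring),
    ROC-based threshold tuning, a seeded negative-binomial simulator of
    hierarchically structured counts with planted marker signal, and a
    command-line interface. Sparse input matrices are never densified
    beyond the classifier feature panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
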