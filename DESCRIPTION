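Package: mirweave
Title: miRNA-mRNA Interactome Inference from Paired Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of paired bulk miRNA and mRNA sequencing
    experiments with a two-group (case versus control) design: median-of-ratios
    normalization, negative-binomial Wald differential expression with
    Benjamini-Hochberg adjustment, hypergeometric over-representation analysis
    against GMT gene-set collections, and construction of a miRNA-mRNA
    regulatory interactome by cascading a target-prediction consensus filter,
    an experimental-validation filter, a shared-target filter and a Pearson
    anti-correlation screen. Includes a synthetic-data generator that plants
    differentially expressed features and anti-correlated miRNA-target pairs
    with full ground truth for pipeline benchmarking, and an end-to-end
    pipeline driver with machine-readable run summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
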