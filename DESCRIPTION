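Package: budsig
Title: Tumor Budding Signature Derivation and Evaluation from Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives gene-expression signatures of tumor budding from
    segment-level spatial transcriptomics data and evaluates them on bulk,
    single-cell and pharmacogenomic expression data. Implements segment
    quality control with negative-probe limit-of-quantification filtering,
    upper-quartile (Q3) normalization, case-level aggregation, paired and
    unpaired Wilcoxon differential expression with intersection-based
    signature derivation, mean-log2 signature scoring, Gaussian-mixture
    bimodal cutoff estimation, fold-change-of-percentages gene-set
    enrichment, differential Spearman correlation networks with a
    permutation null on Fisher-Z differences, ROC classification, survival
    stratification with cutoff optimization, and a signature-drug-response
    screen. A synthetic-data generator reproduces the statistical structure
    of all required inputs so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    survival,
    mclust,
    igraph,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
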