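Package: CAFscape
Title: Single-Cell and Bulk Transcriptomic Dissection of Cancer-Associated
    Fibroblast Heterogeneity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for dissecting cancer-associated fibroblast
    (CAF) heterogeneity in liver metastases from droplet-based single-cell
    RNA-seq: per-sample quality filtering, total-count normalization,
    coefficient-of-variation gene selection, PCA/t-SNE embedding and Ward
    hierarchical clustering into nested main/sub populations; consensus
    marker-gene signature derivation with expression-fraction, fold-change
    and adjusted-p gates; reference-atlas origin classification of CAFs by
    random forest, k-nearest neighbors and linear SVM with repeated
    cross-validation and multinomial composition testing; per-sample
    ligand-receptor crosstalk scoring with median-reliability and
    population-bias selection; and a TMM/negative-binomial differential
    expression and hypergeometric gene-set enrichment stage for bulk siRNA
    silencing experiments. A negative-binomial synthetic-data generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    edgeR,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, GeneExpression, Clustering,
    DifferentialExpression, CellBiology
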