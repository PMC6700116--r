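Package: gliaprog
Title: Gene Programmes, Immune Deconvolution and CNV Inference for
    Low-Grade Glioma Single-Cell RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the cellular composition and expression
    programmes of pilocytic astrocytoma and related low-grade gliomas from
    single-cell RNA-seq. Implements quality filtering and log-normalization,
    covariate regression and scaling, shared-nearest-neighbor clustering of
    principal-component coordinates, per-cluster Wilcoxon marker detection,
    fold-enrichment scoring of gene signatures, derivation of MAPK,
    astrocyte-like and oligodendrocyte-like gene programmes from principal
    component loadings, compartment-signature deconvolution of bulk
    expression into cancer and immune fractions, and inference of large
    copy-number variants by 100-gene windowed expression averaging. A
    negative-binomial synthetic-data generator with full ground truth plants
    the population structure these analyses assume, so every stage is
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
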