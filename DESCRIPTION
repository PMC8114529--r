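Package: slicepharm
Title: Cell Type-Specific Drug Response Deconvolution for Perturbed Tumor Slice Cultures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deconvolves cell type-specific drug responses from single-cell
    RNA-seq of drug-perturbed acute tumor slice cultures. Provides barcode-level
    quality control with UMI address collapse and ambient-aware cell calling,
    aneuploidy-based classification of malignantly transformed cells from
    chromosome 7/10 expression with a double-Gaussian threshold, whole-genome
    sequencing chromosome copy-number estimation, hierarchical Poisson
    factorization of merged count matrices with projection of held-out cells
    and nuisance-factor detection, factor-signature perturbation statistics,
    depth-matched rank-based differential expression with pooled-deconvolution
    normalization, preranked gene set enrichment over factor signatures, and
    Gaussian-mixture intensity thresholds for in situ image quantification.
    Includes a seeded synthetic multi-patient cohort generator with known
    ground truth for validation of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    scran
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, GeneExpression, QualityControl,
    DifferentialExpression, CopyNumberVariation
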