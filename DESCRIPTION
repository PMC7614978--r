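Package: multidrop
Title: Multiomic Droplet QC, CITE-seq Background Correction, Label
    Transfer and Neighborhood Differential Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for droplet-based single-cell multiomics:
    simulation of cell-by-gene and droplet-by-protein count data with known
    ground truth; cell and gene quality-control filters with per-lane
    doublet-cluster removal; library-size normalization and dispersion-based
    highly variable gene selection; empty-droplet discovery from the total-UMI
    distribution followed by DSB-style z-scoring of antibody counts against the
    ambient background, Gaussian-mixture background modeling and per-protein
    background regression; probabilistic multinomial elastic-net label transfer
    with cluster-level voting and coefficient impact scores; KNN-neighborhood
    differential abundance testing across gestational age with FACS sorting-bias
    offsets, negative-binomial GLMs and distance-weighted FDR control; and
    gene-module enrichment scoring with expression-matched control genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    glmnet,
    mclust,
    MASS,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
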