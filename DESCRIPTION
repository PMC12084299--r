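Package: imcniche
Title: Spatial Single-Cell Analysis of Multiplexed Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end spatial single-cell analysis of imaging mass
    cytometry (IMC) data: per-pixel spillover compensation, median
    denoising and linear intensity adjustment; per-cell quantification
    from segmentation label masks; percentile range normalization and
    PhenoGraph-style graph clustering with rule-based phenotype
    annotation; cellular-neighborhood (CN) discovery from spatial
    k-nearest-neighbor composition profiles via k-means; permutation
    tests for pairwise cell-cell spatial interaction and avoidance;
    group-level association analyses (composition, CN abundance,
    density-quartile trends, composition correlations); Voronoi and
    heatmap reporting. Includes a synthetic-tissue cohort simulator
    (Poisson and Neyman-Scott placement, hard-core avoidance, planted
    niches, lognormal marker expression, spillover and counting noise)
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    SingleCellExperiment,
    pracma,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
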