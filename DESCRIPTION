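Package: imcpipe
Title: Optimized Single-Cell and Spatial Analysis of Imaging Mass Cytometry Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning segmented imaging mass cytometry (IMC)
    acquisitions into analysis-ready single-cell data: per-cell feature
    extraction from label masks with hot-pixel capping and spillover
    compensation, arcsinh cofactor optimization driven by the Fisher
    discrimination ratio between negative and positive signal populations,
    Z-score batch normalization, self-organizing-map clustering with
    hierarchical consensus metaclustering, and a permutation-based spatial
    neighborhood analysis using disc or bounding-box pixel expansion.
    Includes a synthetic-tissue simulator with known ground truth, FCS 3.1
    export for downstream cytometry software, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Matrix,
    mclust,
    pracma,
    tiff,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, Spatial, ImagingMassCytometry, Clustering,
    Normalization, Software
RoxygenNote: 7.3.3
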