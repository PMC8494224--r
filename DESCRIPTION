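Package: SpatialScreen
Title: Density-Agnostic Spatial Autocorrelation Analysis for Spatially
    Resolved Transcriptomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies spatially heterogeneous genes in spatially resolved
    transcriptomics data using Moran's I with analytic null moments on a
    binary Delaunay-derived adjacency graph, characterizes pattern scale with
    local indicators of spatial association (LISA), groups genes into primary
    spatial patterns via spatial cross-correlation, infers putative cell-cell
    communication from inter-cell-type spatial cross-correlation of
    receptor-ligand pairs with adaptive permutation testing, and performs
    spatially informed graph-based clustering. The binary neighbor
    representation makes all statistics robust to nonuniform cell densities
    and works in both 2D and 3D.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deldir,
    igraph,
    FNN,
    interp,
    cluster,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
biocViews: Transcriptomics, Spatial, GeneExpression, Clustering,
    SingleCell, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
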