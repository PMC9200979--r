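Package: crc3d
Title: Three-Dimensional Phenotyping of Cassava Root Crowns from Photogrammetry Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for extracting root-system architecture traits from
    photogrammetry-derived triangle meshes of excavated cassava root crowns.
    Provides mesh input/output (OBJ, PLY), watertight repair by volumetric
    remeshing, scale calibration against a cuboid reference object, the
    split-half crown volume protocol, whole-crown traits (volume, surface
    area, diameter, cylinder soil volume, compactness, root density,
    surface-to-volume ratio), digital dissection of individual storage roots
    (length, basal angle, diameter), a procedural synthetic-crown generator
    with voxel-oracle ground truth for benchmarking, and the downstream
    field-trial statistics (validation regression, trait correlations, PCA,
    augmented RCBD adjusted means and broad-sense heritability).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
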