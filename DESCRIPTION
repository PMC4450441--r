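Package: rootquant
Title: Cell-Resolution Quantification of Nuclear Reporter Expression in
    Root Meristem Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation, 3D reconstruction and per-cell fluorescence
    quantification of plant root meristems imaged as multi-channel confocal
    z-stacks. Cell walls are segmented plane-by-plane (Gaussian smoothing,
    median-based local thresholding, skeletonization and flood-fill
    labelling), 2D regions are linked across neighbouring planes into 3D
    cells using centroid-distance and relative-area criteria, and mean
    nuclear reporter intensity is computed per reconstructed cell with a
    depth-based exclusion for photobleaching. Downstream tools classify
    cells into ON/OFF expression states with a Gaussian mixture model,
    quantify clonal cell-file coherence, and test cis versus trans
    epigenetic memory from two-reporter state calls. A synthetic
    root-meristem generator with voxel-level ground truth supports
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    EBImage,
    mclust,
    jsonlite,
    tiff,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
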