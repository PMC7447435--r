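Package: tissueseg
Title: Volumetric Cell Segmentation via Boundary Prediction and Graph Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step instance segmentation of densely packed cells in 3D (and 2D)
    membrane-stained microscopy volumes. A compact convolutional network (plain or
    residual U-Net, CPU implementation with explicit backpropagation) predicts
    per-voxel cell-boundary probabilities; a distance-transform watershed clusters
    voxels into supervoxels; and a region adjacency graph built on the supervoxels
    is partitioned with agglomerative average linkage (GASP), the mutex watershed,
    or greedy multicut to produce the final labeling. Includes the standard
    evaluation metrics for instance segmentation (adjusted Rand error, variation
    of information split/merge, boundary precision-recall curves, PSNR, SSIM), a
    synthetic Voronoi tissue generator for development and testing, HDF5/TIFF
    input and output, and a YAML-driven pipeline runner with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    rhdf5,
    tiff,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
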