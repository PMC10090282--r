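Package: canopyprint
Title: Canopy Fingerprints from Terrestrial Laser Scanning Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for turning terrestrial laser scanning
    (TLS) point clouds of row-crop canopies into multi-scale, interpretable
    "canopy fingerprints". Covers point-cloud I/O (PCD, PLY, CSV), density
    homogenization by voxel downsampling, statistical outlier removal,
    reference-marker detection and block cropping, sphere-target rigid
    registration with optional ICP refinement, ground-plane fitting and
    per-plot canopy segmentation, 3D and projected-2D geometric trait
    extraction (height, watertight-mesh volume and surface area, outline
    area, aspect ratio, roundness, circularity, solidity), and generation,
    querying and clustering of center-slice-normalized sub-canopy feature
    vectors. A seeded synthetic-scene generator (parametric canopy solids,
    hill-plot field scenes with spherical reference markers, multi-view scan
    simulation) makes the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    data.table,
    Rcpp,
    RANN,
    deldir,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'canopyprint-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'pointcloud.R'
    'preprocess.R'
    'segment.R'
    'traits.R'
    'outline.R'
    'fingerprint.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
    'register.R'
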