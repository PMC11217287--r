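Package: seedmech
Title: Shape-Driven Stress, Curvature and Microtubule Orientation Analysis for Seed Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying how organ shape prescribes
    mechanical stress patterns and cortical microtubule (CMT) organization
    during Arabidopsis seed morphogenesis. Provides a linear membrane
    finite-element solver for pressurized triangulated shells with
    closed-form spheroid oracles, per-cell principal-curvature estimation on
    surface meshes by local quadric fitting, nematic-tensor quantification
    of fibril orientation and organization in 2D images, organ- and
    cell-scale growth morphometry (segmentation, ellipse fitting,
    growth-rate and growth-anisotropy series with propagated standard
    deviations, lineage-based cell growth maps), and a synthetic-data
    module that generates seed-shaped ellipsoid meshes, cell tessellations,
    oriented fibril textures, axially distributed CMT fields, seed
    silhouettes and growth series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    igraph,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'angles.R'
    'mesh.R'
    'tessellation.R'
    'shell-fem.R'
    'curvature.R'
    'cmt-field.R'
    'fibril.R'
    'utils.R'
    'growth.R'
    'morphometry.R'
    'synth-images.R'
    'regions.R'
    'pipeline.R'
    'seedmech-package.R'
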