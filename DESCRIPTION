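Package: spinemorph
Title: 3D Dendritic Spine Morphometry, Clustering and Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantitative morphometry of dendritic
    spines reconstructed from confocal image stacks. Provides segmentation of
    deconvolved volumes by morphological active contours without edges,
    isosurface reconstruction with anisotropic voxel spacing, a mesh
    optimization and repair loop, ten morphometric descriptors of single-spine
    meshes (length, surface, volume, convex-hull volume and ratio, distance
    statistics, open angle, and discrete mean and Gaussian curvature),
    correlation-based feature pruning, principal component analysis, K-means
    clustering with cluster-number selection, and the group-comparison
    statistics used in spine plasticity studies (Agresti-Caffo two-proportion
    tests, Cohen's d, one-way intraclass correlation, kernel-density shift
    maps). A synthetic spine generator with analytic ground truth makes every
    stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    MASS,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
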