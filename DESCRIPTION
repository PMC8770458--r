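Package: mitomorph
Title: 3-D Morphometry and Unbiased Stereology of Cardiac Mitochondrial
    Subpopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cardiac mitochondrial remodelling from
    3-D electron-microscopy label volumes and 2-D TEM images. Implements
    per-mitochondrion morphometry (volume, surface area, shape
    classification, tubular-projection and nanotunnel detection) on
    anisotropic voxel rasters, two-lattice unbiased stereological point
    counting for mitochondrial volume fractions and subpopulation
    densities, test-line estimation of cristae surface density, and
    line-profile measurement of cristae membrane-doublet dimensions.
    Includes a seeded synthetic cardiomyocyte phantom generator with
    exhaustive ground truth so that every estimator can be validated
    against known geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    tiff,
    EBImage,
    emmeans,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
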