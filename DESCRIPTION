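Package: rimmorph
Title: 3D Cellular Morphometry for Membrane-Labeled Nematode Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative 3D cell-shape analysis of early
    Caenorhabditis elegans embryos imaged with membrane markers under
    refractive-index-matched media. Implements a ground-truthed synthetic
    embryo stack generator with tunable spherical-aberration-like
    degradation, a DIC contrast model for refractive-index matching
    assays, depth-attenuation correction, tolerance-based
    marker-controlled 3D watershed segmentation with quality scoring,
    per-cell morphometry (volume, marching-tetrahedra surface area,
    sphericity, second-moment ellipsoid fits, STL surface models), and a
    2D boundary-tension cell-shape relaxation model that reproduces
    germline-precursor rounding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    withr,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
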