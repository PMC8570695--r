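Package: epitopo
Title: 3D Cell-Neighbour Organisation in Pseudostratified Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of three-dimensional cell-neighbour organisation in
    pseudostratified epithelia from labelled cross-section stacks or tidy
    per-layer tables. Provides per-layer polygonal lattice statistics
    (Euler's topological mean, Lewis' law, the Aboav-Weaire law, hexagon
    fraction versus area coefficient of variation), detection and Poisson
    statistics of lateral T1 neighbour exchanges along the apical-basal
    axis, an ellipse-based local tissue-curvature model with per-transition
    curvature fold changes, nuclear morphometrics coupled to interkinetic
    nuclear migration, and a synthetic pseudostratified-epithelium
    generator built on a rasterised power-diagram tessellation for fully
    reproducible testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
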