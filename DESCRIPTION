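Package: semiland
Title: High-Density Sliding and Surface Semilandmark Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-density three-dimensional geometric morphometrics
    built around template-based projection ("patching") of surface
    semilandmarks onto specimen meshes, sliding of curve and surface
    semilandmarks by bending-energy or Procrustes-distance minimization, and
    generalized Procrustes alignment with principal component analysis.
    Includes triangle-mesh input/output for PLY and STL dialects, thin-plate
    spline warping with the bending-energy quadratic form, procedures for
    variably present structures (negligible regions and negligibly sized
    holes), bilateral mirroring of one-sided data, piecemeal patching and
    sliding, and evaluation utilities (landmark sampling curves, random
    skewers covariance correspondence, and Procrustean fit between datasets).
    Deterministic synthetic-fixture generators (pyramidal specimens with
    optional fossae, hemispherical templates, bilateral and two-group
    datasets) make the whole pipeline testable without external scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
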