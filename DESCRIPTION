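Package: cpetnull
Title: Null-Function Analysis for Charged-Particle Emission Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models, symmetry-reduced singular-value analysis and
    null-function decomposition for charged-particle emission tomography
    (CPET) with planar particle-processing detectors. Provides an analytic
    straight-line transport model for alpha emitters, a condensed-history
    Monte Carlo for beta particles in water, list-mode event handling and
    histogramming, construction of the depth kernel K(rho, z, z') of the
    projection/backprojection operator, its per-frequency eigendecomposition,
    and the decomposition of voxelized test objects into measurement and null
    components for detectors that measure 2 to 5 particle attributes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
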