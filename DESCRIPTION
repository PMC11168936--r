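Package: gutmorph
Title: Morphometrics of Tubular Organ Centrelines, Surfaces and Intensity
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative 3D morphometrics for tubular organs traced from
    volumetric images, motivated by the looping adult Drosophila gut.
    Estimates curvature, torsion, radius and tilt along arclength-
    parameterized centrelines via local cubic fits and the Frenet-Serret
    relations; runs generalized Procrustes alignment, shape PCA and
    Procrustes type III ANOVA with residual randomization (RRPP) on
    equally spaced pseudolandmarks; compares curvature functions across
    specimens with elastic (square-root-slope / Fisher-Rao) registration,
    a discretized curvature distance, metric multidimensional scaling,
    confidence ellipsoids and location tests; maps interorgan proximity
    from triangular surface meshes; and correlates arclength intensity
    profiles with curvature against an autoregressive null. Includes a
    seed-deterministic synthetic cohort generator (sex-dimorphic
    centrelines, tube meshes, intensity traces) so the full pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
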