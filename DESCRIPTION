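Package: pfnets
Title: Multi-Scale Personalized Functional Brain Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives personalized functional brain networks from surface
    fMRI timeseries at multiple scales using spatially regularized,
    group-consensus non-negative matrix factorization, and analyses their
    between-network coupling along the sensorimotor-to-association cortical
    hierarchy. Includes bootstrap atlas construction fused by spectral
    clustering, network/edge/vertex coupling metrics, topographic
    variability maps, spherical spin tests, penalized-spline age and
    cognition models with generalized estimating equations across scales,
    ridge-based prediction of executive function, and a synthetic cortical
    cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    mgcv,
    clue,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
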