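Package: ontomorph
Title: Ontogenetic Shape Analysis with Geometric Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying ontogenetic shape change in 2D landmark data.
    Implements Generalized Procrustes Analysis with sliding semilandmarks
    (bending-energy criterion), thin-plate-spline bending energy and partial
    warps, Procrustes ANOVA with residual randomization permutation (RRPP)
    tests, pairwise allometric-slope comparison, phenotypic trajectory
    analysis across developmental stages, Procrustes-variance disparity,
    the covariance-ratio (CR) modularity test and the global integration
    (GI) coefficient. Includes a synthetic-data generator that emulates a
    multi-species, multi-stage ontogenetic sampling design so every stage
    of the pipeline can be validated against known ground truth, and a
    one-call pipeline that reproduces the full analysis graph with
    fixed-seed determinism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
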