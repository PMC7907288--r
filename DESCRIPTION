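Package: morphoscore
Title: Landmark-Based Morphometric Analysis of Dysmorphology and Treatment Effect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Statistical shape analysis of 3D anatomical landmark configurations
    for quantifying facial dysmorphology and scoring treatment effect.
    Implements generalized Procrustes superimposition with allometric
    correction by multivariate regression of shape on age, principal component
    ordination with convex-hull range-of-variation membership, Euclidean
    Distance Matrix Analysis (EDMA) with non-parametric bootstrap
    confidence-interval testing of all unique inter-landmark distances,
    a facial treatment score (FTS) with an iterative scaffolded-bootstrap
    significance test, permutation tests on Procrustes distances between
    group mean shapes, and a synthetic landmark-cohort generator with known
    ground truth for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
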