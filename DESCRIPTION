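Package: wmhconn
Title: Age, White-Matter Hyperintensities, Fluid Cognition, and the
    Structural Connectome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for studying how white-matter
    hyperintensity (WMH) load relates to age, fluid cognition, and the
    weighted structural connectome in adult-lifespan cohorts.  Provides
    principal-axis factor scoring of a 12-test cognitive battery with
    covariate control, zero-order and partial correlation tables with
    false-discovery-rate adjustment, cross-validated multivariate partial
    least squares regression (SIMPLS) on vectorized 246-node connectomes
    with permutation-null resampling and subnetwork edge masks,
    graph-theoretic network metrics (density, weighted clustering,
    modularity with a-priori and consensus partitions, communicability),
    bootstrap mediation models, and a seeded synthetic-cohort generator
    that emulates the joint age-cognition-WMH-connectome structure for
    testing every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
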