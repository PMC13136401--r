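Package: crosslex
Title: Cross-Linguistic Semantic Spaces, Universality Metrics, and Environmental Representational Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how word meanings align and vary across
    languages. Builds comparable semantic spaces from per-language word
    embeddings by anchor-word projection (a 13-dimension neurocognitive
    model plus distributional, feature-based, and two random control
    models), quantifies cross-language commonality with Fisher-z
    inter-language correlations and PCA against permutation null
    benchmarks, derives concept-pair similarity from colexification
    network topology (edge weight, weighted common neighbours, Louvain
    and Infomap community structure), computes environmental distance
    matrices (bioclim climate, great-circle geography, family-tree
    steps, participant demographics), and relates semantic, behavioural
    and neural representational dissimilarity matrices to environment
    with crossed family-random-intercept mixed models, hierarchical
    regression, commonality variance partitioning, and climate
    principal-component semantic projection. A seeded synthetic-world
    generator with planted effect sizes supports parameter-recovery and
    calibration testing of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    igraph,
    ape,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
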