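Package: puddleclass
Title: Community Classes, Distance Decay and Functional Path Models for
    Tree-Hole Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A top-down analysis toolkit for bacterial community surveys:
    beta-diversity dissimilarities (Jensen-Shannon divergence and a
    SparCC-derived compositional distance), Mantel tests, multi-scale
    distance-decay scans built on from-formula implementations of ANOSIM,
    MRPP and PERMANOVA, unsupervised community-class detection by
    partitioning around medoids with Calinski-Harabasz model selection,
    classification agreement measures, and multi-group recursive path
    models over community functional measurements with AIC-guided
    constraint selection, backdoor adjustment sets and class-interaction
    regressions. Includes seeded generators for class-structured
    Dirichlet-multinomial communities driven by a succession process,
    scenario-controlled artificial dissimilarity matrices, and functional
    measurements drawn from a known path model, plus an end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
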