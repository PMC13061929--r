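Package: orotyper
Title: Community Typing, Co-Occurrence Networks and Classification for Tongue Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genus-level oral (tongue) microbiota
    profiles. Classifies samples into community types ("orotypes") by
    Jensen-Shannon distance, partitioning-around-medoids clustering and
    Calinski-Harabasz model selection; builds compositionality-corrected
    co-occurrence networks using a permutation-renormalization null with
    Benjamini-Hochberg FDR control and edge-betweenness community
    detection; trains and evaluates a multinomial logistic orotype
    classifier with one-vs-rest ROC-AUC and stepwise backward feature
    elimination; computes orotype-covariate association statistics and
    longitudinal orotype-trajectory summaries. Includes a Dirichlet
    logistic-normal synthetic cohort generator so the whole pipeline is
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    ape,
    biomformat,
    cluster,
    jsonlite,
    nnet,
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
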