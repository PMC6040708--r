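Package: corrscape
Title: Corridor Connectivity of Linear Landscape Elements via Circuit
    Theory and Floristic Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether linear landscape elements (field margins,
    ditches, hedges) act as dispersal corridors for vascular plants. Converts
    mapped linear elements to 1-m resistance rasters, computes circuit-theory
    effective resistance between vegetation plots over the element network,
    builds within-area plot-pair tables with group-wise Jaccard similarities,
    and compares the effects of resistance distance and Euclidean distance on
    similarity with binomial logit mixed models (crossed random intercepts,
    observation-level effects for overdispersion, parametric-bootstrap term
    tests). Includes simple-slope and slope-difference statistics, predicted
    similarity gains translated into counts of shared species, and a seeded
    synthetic landscape and community generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    lme4,
    Matrix,
    minqa,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
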