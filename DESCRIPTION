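Package: xknet
Title: Cross-Kingdom Microbial Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and interpreting cross-kingdom
    (bacterial-fungal) microbial co-occurrence networks. Includes a
    generalized Lotka-Volterra community simulator (random subset
    integration to steady state, multinomial read sampling), ridge
    regression inference of growth rates and the community matrix with
    sign-pattern interaction classification, signed correlation network
    construction with BH control, node and network topology statistics,
    in-silico extinction experiments with secondary extinctions and
    robustness AUC, degree-preserving and curveball null models with
    Z-score normalization (including the divide-by-mean rule for
    zero-variance ensembles), and NODF bipartite nestedness with a
    fixed-margins permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
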