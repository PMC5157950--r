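Package: sporecycle
Title: Growth-Starvation Cycle Simulation of Social Amoeba Life Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Socially-neutral eco-evolutionary simulator for sporulating
    social amoebae (Dictyostelium-like life cycles). Genotypes defined by a
    division rate and an aggregation strategy (a discrete aggregating
    fraction or a continuous aggregation rate) compete for a shared resource
    through repeated growth-starvation cycles with Michaelis-Menten resource
    uptake, Weibull-type survivorship of starving solitary cells, dormant
    spore decay, and germination lag and viability costs. Includes long-run
    winner determination in deterministic and stochastic (exponential
    starvation time) environments, single-cycle laboratory assay emulations
    (clonal trait correlations, pairwise chimeric success, dominance
    hierarchies and their transitivity), configuration handling, seeded
    reproducible runs, and CSV/JSON result export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
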