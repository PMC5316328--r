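Package: gooseAHM
Title: Adaptive Harvest Management for the Svalbard Pink-Footed Goose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-model adaptive harvest management (AHM) of the
    Svalbard-breeding pink-footed goose (Anser brachyrhynchus). Implements a
    nine-model set of annual population dynamics driven by spring temperature
    (days above freezing in May in Svalbard) and density dependence, Bayesian
    updating of model weights from spring population counts, stochastic
    dynamic programming (value iteration) of state-dependent harvest quotas
    against a population-target utility, a regression-tree summary of the
    policy table, annual assessment with quota allocation between Norway and
    Denmark and emergency-closure logic, Chapman mark-resight abundance
    checks, open-loop stochastic projections, closed-loop management strategy
    evaluation, and a synthetic monitoring-data generator calibrated to the
    programme's published trajectory facts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
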