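Package: drivewave
Title: Spatial Stochastic Simulation of Sex-Distorter Suppression Gene Drives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based stochastic simulation of X-shredder and
    W-shredder suppression gene drives spreading through a wild-type
    population on a bounded one-dimensional landscape, with Beverton-Holt
    local density regulation, Gaussian dispersal and a mate-finding Allee
    effect. Includes the matching deterministic allele-frequency recursions
    and Fisher-KPP wave-speed theory for both drive systems, measurement of
    emergent invasion-wave properties (velocity, height, width), detection
    of wild-type penetration, chasing and drive-loss events, outcome
    classification, scenario-grid experiments, width-scaling regressions and
    logistic event models with ROC AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
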