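Package: evorescue
Title: Individual-Based Simulation of Evolutionary Rescue Under Structured
    Habitat Loss and Environmental Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit, non-Wright-Fisher individual-based
    simulations of diploid populations locally adapted to a spatially
    autocorrelated environmental gradient on a periodic (torus) landscape,
    subjected to structured habitat loss and gradual warming. Provides
    periodic Gaussian random field landscape generators, quantile-threshold
    habitat-loss maps with controlled autocorrelation, landscape-property
    metrics (trimmed environmental breadth loss, mean environmental shift,
    loss autocorrelation length, Geary's C), weighted density sampling of
    loss scenarios, a polygenic-trait individual-based model with local
    competition, nearest-neighbour mating and habitat choice, per-scenario
    persistence outcomes, and hierarchical Bayesian logistic regression of
    persistence on landscape properties.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rjags,
    coda,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
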