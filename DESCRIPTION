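Package: ibdclt
Title: Coalescent Models and Normality Diagnostics for Identity-by-Descent
    Rates Around a Locus
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative model of identity-by-descent (IBD) segments around a
    focal locus: Kingman coalescent genealogies under piecewise-constant
    demography, crossover recombination as a Poisson process, and detection
    indicators for segment extents exceeding a Morgans threshold. Provides
    closed-form and numerically integrated moments of detectable IBD rates,
    central-limit-theorem condition diagnostics, detectable-IBD graphs at a
    locus with connected-component features, matched sparse Erdos-Renyi
    comparisons, and Shapiro-Wilk / upper-percentile simulation batteries,
    behind both an R API and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
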