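Package: uniflex
Title: Building and Evaluating Consensus Genomic Interval Universes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing consensus genomic region sets ("universes")
    from collections of BED-style interval sets, and for evaluating how well a
    universe fits a collection. Supports flexible intervals whose start and end
    boundaries are intervals rather than points, builders based on coverage
    cutoffs, a maximum-likelihood label path, and a hidden Markov model over
    base-resolution start/coverage/end signal tracks, and three fit metrics:
    base-level F10 overlap, region boundary distance, and universe likelihood,
    each with a flexible-aware variant. Includes a seeded synthetic-collection
    generator for testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
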