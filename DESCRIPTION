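Package: itmflow
Title: Context-Specific Information Flow in Weighted Directed Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Damped discrete-time random walks on weighted directed graphs
    for extracting context-specific subnetworks (information transduction
    modules, ITMs). Given a network, a set of boundary nodes (sources
    and/or sinks) and a dissipation probability, the package solves the
    emitting, absorbing and normalized-channel flow models as sparse
    absorbing-Markov-chain linear systems, calibrates the damping factor
    from a target mean path length or mean absorption probability by
    safeguarded Newton iteration, ranks nodes by visit counts or
    absorption probabilities, selects significant nodes by participation
    ratio, cutoff or top-k, and exports results as round-trippable
    tab-delimited files. A Monte Carlo walker simulator serves as an
    independent verification oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
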