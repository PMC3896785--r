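Package: kinmotif
Title: Kinetic Motif Discovery in Adaptive Enzyme Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global profiling of kinetic parameters in three-node enzyme
    networks that exhibit perfect adaptation, such as the negative-feedback
    circuit underlying Escherichia coli chemotaxis. The package samples
    Michaelis-Menten kinetic parameters by Latin hypercube on a log10 scale,
    simulates pre- and post-stimulus dynamics of the network to score
    sensitivity and precision of the step response, detects "kinetic motifs"
    (decade-wide value classes over-represented among adapting parameter
    sets) with a hypergeometric enrichment test, and associates each motif
    with the sensitivity or precision phase of the dynamics through
    Mann-Whitney rank tests, a bipartite kinetic-functionality network, and
    pairwise Pearson cooperation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
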