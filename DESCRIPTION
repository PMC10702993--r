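Package: sipinrs
Title: Emotional Contagion Dynamics with Positive and Negative Disseminators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spread of positive and negative sentiment through an
    online population with the SIpInRS compartmental model: a mean-field system
    of ordinary differential equations with equilibrium and contagion-threshold
    analysis, a classical SIRS comparator, and a stochastic agent-based
    extension on complex networks (small-world, scale-free, or empirical edge
    lists) in which per-node transition probabilities are driven by the
    imbalance of neighbor-degree sums between the two emotional camps. Includes
    generators and summary statistics for Watts-Strogatz and Barabasi-Albert
    networks, a catalog of reference parameter scenarios, peak detection, and
    trajectory comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
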