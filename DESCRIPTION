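Package: circuitdesign
Title: Sequential Bayesian Optimal Experimental Design for Gene-Circuit
    Kinetic Parameter Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-theoretic sequential experimental design for kinetic
    parameter estimation in ordinary-differential-equation models of gene
    regulatory circuits. Simulates Hill-regulated mRNA/protein dynamics under
    perturbations (gene deletion, mRNA knockdown, ribosomal-activity
    decrease), enumerates a costed catalogue of purchasable experiments,
    samples multimodal posteriors by multi-start quasi-Newton mode finding
    followed by Metropolis-Hastings with mixture-based chain recombination,
    scores every candidate experiment by a Monte-Carlo estimate of its
    expected posterior loss, and runs a budgeted greedy design loop with a
    random-design baseline for comparison.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
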