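Package: quorumsig
Title: Evolutionary Dynamics of Quorum Signaling in N-Person Collective Action Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how costly signaling systems evolve in finite
    populations facing an N-person threshold public goods game with two states
    of Nature. Strategies encode a signal for each state and an action for
    each majority group signal. The package computes exact expected payoffs
    under hypergeometric group sampling, fixation probabilities under the
    pairwise-comparison (Fermi) birth-death process, the small-mutation-limit
    embedded Markov chain over monomorphic states with its stationary
    distribution, evolutionary-robustness classifiers and invasion graphs,
    together with a stochastic birth-death simulator with mutation that acts
    as an independent check on the analytics. Parameter sweeps reproduce the
    prevalence maps and threshold relations of the underlying model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
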