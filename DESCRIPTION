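Package: cyclefix
Title: Origin-Fixation and Wright-Fisher Models of Grammaticalisation Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how individual speaker behaviour drives
    population-scale language change, using the four-stage grammaticalisation
    cycle of definite and indefinite articles as the model system. Provides a
    population-scale origin-fixation (semi-Markov) model with Poisson
    origination and Gamma-distributed fixation times, an individual-based
    Wright-Fisher simulator on heterogeneous social networks together with
    its diffusion approximation (fixation probabilities, conditional
    fixation-time moments, effective population sizes), likelihood-based
    comparison of child-based, usage-based and network-structured theories of
    language change via AICc, overdispersion and Monte Carlo p-values, and a
    synthetic-corpus generator emulating surveys of dated language histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
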