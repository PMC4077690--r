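Package: pbnfit
Title: Probabilistic Boolean Networks: Simulation, Steady States and
    Selection-Probability Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building probabilistic Boolean networks (PBNs) from
    rule-based Boolean model specifications, simulating them as ergodic Markov
    chains with per-node perturbation and input clamping, estimating marginal
    steady-state probabilities with the two-state Markov chain run-length
    method, and fitting the selection probabilities of candidate Boolean rules
    to multi-experiment steady-state measurements by minimising the sum of
    squared errors, in either a discrete (rule selection) or continuous
    (probability inference) mode. Includes an exact transition-matrix oracle
    for small networks, ensemble statistics for identifiability assessment,
    and generators for bundled case-study models and data.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
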