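Package: plastevo
Title: Evolving Plastic Neural Networks with Developmental Encodings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolving artificial neural networks with
    neuromodulated Hebbian plasticity on a simulated Skinner-box
    (operant conditioning) task. Provides the plastic neuron model,
    three genetic encodings (direct graph, map-based developmental,
    and a minimal HyperNEAT variant driven by compositional
    pattern-producing networks), multi-objective evolution with
    NSGA-II and behavioral novelty, a General Learning Abilities
    score over the complete set of stimulus-action association sets,
    and an exact graph-automorphism regularity measure for developed
    networks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
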