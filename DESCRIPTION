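Package: microcausal
Title: Causal Discovery Benchmarks for Cross-Sectional Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation benchmarks for causal discovery from cross-sectional
    microbiome abundance data. Provides directed-acyclic-graph machinery
    (d-separation, CPDAG computation via Meek closure, Markov equivalence
    class enumeration, the backdoor criterion), random linear-Gaussian
    structural causal models over OTU abundance variables, the stable PC
    algorithm with the Fisher-z partial correlation test, the IDA estimator
    of intervention effects with its minimum-absolute-value summary and its
    infinite-sample oracle variant, labelled DAGs encoding context-specific
    independence with Dirichlet-multinomial Bayesian structure scoring for a
    two-OTU community-effect model, exact backdoor adjustment for discrete
    systems, and configurable experiment harnesses that reproduce discovery
    rates under forward and reversed causal mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
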