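Package: choqmd
Title: Choquet-Integral Fuzzy Aggregation of Atomic Contributions into
    Molecular Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes global molecular descriptors by fuzzy (non-additive)
    aggregation of atom-level contributions (local vertex invariants, LOVIs)
    with the Choquet integral. Implements the closed-form L-m-delta fuzzy
    measure, the Sugeno lambda- and P-measures, AO1/AO2 singleton-density
    generators, fuzzy extensions of classical topological indices (Zagreb,
    Randic, Balaban-like, Kier-Hall, autocorrelation) and geometric
    two-linear descriptors built from inter-atomic relation matrices with
    stochastic normalizations and Hadamard powers. Also provides the QSAR
    validation statistics (Q2 leave-one-out, bootstrap and external,
    Y-scrambling, GA-MLR variable selection, Friedman first-step ranks,
    exact Wilcoxon signed-rank test) used to compare fuzzy against
    non-fuzzy descriptor models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
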