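Package: ilsbn
Title: Iterated Local Search with Momentum for Bayesian Network Structure
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Score-based structure learning for discrete Bayesian networks
    by iterated local search over the space of directed acyclic graphs.
    Provides three acyclicity-preserving structure perturbation operators
    (Leaf, Root and Swap), a compound Momentum perturbation built from
    them, and search drivers (hill climbing, ILSG and ILSM with a stride
    schedule, Momentum triggering and restarts) optimising the decomposable
    BIC score with a local-score cache.  Also includes structural
    evaluation metrics (SHD and the balanced scoring function BSF),
    ancestral sampling from discrete Bayesian networks, BIF and edge-list
    input/output, and exhaustive verification utilities for the operators'
    acyclicity guarantees.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
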