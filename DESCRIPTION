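Package: sagapath
Title: De Novo Discovery of Mutated Driver Pathways in Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate cancer driver pathways de novo from a binary
    somatic mutation matrix by solving the maximum weight submatrix problem,
    which rewards gene sets that cover many patients while keeping mutations
    mutually exclusive. Provides the coverage/exclusivity weight function, an
    integrative score combining mutation and expression data through pairwise
    Pearson correlation, a simulated annealing hybrid genetic algorithm (SAGA)
    optimizer with genetic-algorithm and Markov chain Monte Carlo baselines, an
    exhaustive exact oracle, a synthetic benchmark generator with implanted
    pathways, permutation-based significance testing, and an iterative
    remove-and-rediscover workflow.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
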