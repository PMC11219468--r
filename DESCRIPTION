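Package: troplr
Title: Tropical Logistic Regression for Phylogenetic Tree Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Logistic regression for sets of phylogenetic trees represented as
    dissimilarity maps in the tropical projective torus. Provides the tropical
    (Generalized Hilbert projective) metric, the tropical Laplace distribution
    with an exact rejection sampler, conversion between rooted equidistant
    trees and ultrametric cophenetic vectors, tropical Fermat-Weber (geometric
    median) estimation with an integer-subgradient optimality certificate and
    a linear-programming oracle, one-species and two-species tropical logistic
    models with closed-form generalization-error formulas and bounds, Gamma
    distance-distribution diagnostics, ROC/AUC evaluation, Yule species-tree
    and multispecies-coalescent gene-tree simulators, and an AUC-based
    convergence diagnostic for paired Bayesian MCMC tree chains alongside a
    reimplementation of the average standard deviation of split frequencies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    grDevices,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
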