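Package: cimcdp
Title: Coherent Ising Machine Hybrid Solvers for L0-Regularised Compressed Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates quantum-classical hybrid solvers for L0-regularised
    compressed sensing, in which a coherent Ising machine (CIM), modelled by
    Wigner or positive-P stochastic differential equations with either
    open-loop or chaotic-amplitude-control (CAC) feedback, estimates the
    binary support of a sparse signal while a classical digital processor
    solves the restricted least-squares subproblem, the two alternating until
    convergence. Includes a random-instance generator for Gaussian
    compressed-sensing problems, simulated-annealing and LASSO (FISTA)
    baselines, and a sparse-MRI reconstruction pipeline built on orthogonal
    Haar wavelets, undersampled k-space operators and synthetic phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse,
    jsonlite
Config/testthat/edition: 3
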