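Package: emps
Title: Particle-Smoother EM Inference of Nonlinear Biochemical Networks
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Data-driven inference of nonlinear biochemical reaction network
    models from heterogeneous single-cell time-course data.  Implements
    maximum-likelihood estimation in nonlinear Gaussian state-space models
    by an expectation-maximization algorithm whose E-step is approximated
    with a particle smoother (EM-PS), and network-topology inference by
    L1 (Lasso) regularization of Hill-function association constants in an
    over-complete "redundant" model (EM-PS-Lasso).  Includes a chemical
    Langevin simulator (stochastic Runge-Kutta) for generating synthetic
    single-cell datasets from reference gene-circuit oscillators, a
    lambda-sweep model-selection procedure with a consistency filter, and
    reporting utilities for parameter-recovery and sweep summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
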