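Package: polkin
Title: Transient-State Kinetic Analysis of RNA Polymerase Multi-Nucleotide
    Addition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and global fitting of transient-state (quench-flow)
    multi-nucleotide addition time courses for RNA polymerases I, II and III.
    Provides declarative first-order kinetic schemes (irreversible elongation
    chains with intrinsic nuclease cleavage, off-pathway paused states,
    reversible pyrophosphorolysis-competent chains, and inactive-subpopulation
    activation), an exact linear-system solver with a Bateman closed-form
    oracle, a synthetic replicate-data generator emulating the gel band-fraction
    observable, a hybrid genetic-algorithm / nonlinear-least-squares global
    fitter with per-replicate aggregation, AICc-based kinetic model comparison,
    and analysis of RNase-protection elongation-complex stability assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    deSolve,
    Matrix,
    lhs,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
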