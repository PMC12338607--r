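Package: normcircuit
Title: Hierarchical Divisive-Normalization Circuit Models of Inter-Areal
    Cortical Communication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construct and analyze hierarchical recurrent neural circuit
    models that implement divisive normalization dynamically across
    reciprocally connected cortical areas (e.g. V1-V2, or V1 with V4 and
    V5). Ring-geometry networks of four cell types (principal, modulatory
    excitatory and two modulatory inhibitory populations) are built from
    orientation tuning curves, center-surround recurrent kernels and
    diagonally dominant inter-areal feedback matrices. The package solves
    the deterministic dynamics and their normalization fixed points,
    linearizes around them, and derives closed-form observables: power
    spectral densities via the resolvent formula, inter-areal coherence,
    stationary covariance via the Lyapunov equation, reduced-rank
    communication-subspace analytics, and their frequency decomposition.
    A compiled Euler-Maruyama simulator provides an empirical oracle for
    every analytic quantity.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
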