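Package: alchemTI
Title: Adaptive Serial-Tempering Thermodynamic Integration on Analytic Model Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expanded-ensemble alchemical free energy calculations on analytic
    model systems with known free energy differences. Implements serial
    tempering along the coupling parameter lambda with a Simpson-rule bias
    built from the running mean of dU/dlambda, variance-adaptive resampling
    (variance-proportional target probabilities with a minimum-probability
    floor, and Neyman sample allocation), Hamiltonian replica exchange between
    independent walkers, and a two-state torsion-scaling enhanced-sampling
    scheme that removes torsional barriers in a dummy state. Free energies are
    estimated by thermodynamic integration with composite quadrature, and a
    full diagnostic stack (autocorrelation, statistical inefficiency,
    effective sample size, standard errors, and an inter-replicate
    sampling-quality ratio) assesses convergence. Monte Carlo propagation
    kernels are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
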