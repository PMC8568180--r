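Package: isingcsd
Title: Critical Slowing Down and Transition Prediction in Ising-Type Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulators and estimators for anticipating critical transitions
    in bistable systems, built around two representations of the Ising model:
    a mean-field stochastic difference equation and a 2D-lattice Metropolis
    Monte Carlo model. Implements perturbation-recovery experiments, a
    critical-slowing-down bifurcation estimator that linearly extrapolates
    maximal recovery rates to the parameter value where recovery vanishes,
    an equilibrium-curve approximation variant, and the classical
    early-warning-signal indicator suite (lag-1 autocorrelation, standard
    deviation, skewness, kurtosis, detrended fluctuation analysis, spectral
    reddening) over rolling windows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
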