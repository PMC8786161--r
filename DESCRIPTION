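Package: socrcc
Title: Controlled Self-Organised Criticality in Networks of Rate-Controlled
    Chaotic Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of chaotic Berry bienzymatic oscillators
    stabilised by Rate Control of Chaos (RCC) and the analysis pipeline for
    their controlled self-organised criticality: fixed-step Runge-Kutta
    integration with epoch-wise random perturbations and instantaneous
    global feedback, per-epoch peak extraction and orbit classification,
    local Lyapunov estimation, power-law maximum-likelihood fitting with
    KS-selected lower cutoff, and power/exponential curve fits with
    MSE-based information criteria.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
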