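Package: resurgentsim
Title: Markov-Model Simulation and Kinetic Analysis of Resurgent Sodium
    Currents in Nav1.7 Channelopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Temperature-dependent Markov modelling of wild-type and
    inherited-erythromelalgia (IEM) mutant Nav1.7 sodium channels.
    Simulates whole-cell voltage-clamp protocols by the Q-matrix
    (matrix-exponential) method, provides the standard patch-clamp
    kinetic-analysis toolbox (Boltzmann activation/inactivation fits,
    window currents, sustained/peak ratios, resurgent-current metrics,
    recovery-from-inactivation fits), generates seeded synthetic
    recordings for parameter-recovery testing, and couples the channel
    model into a two-compartment myelinated-axon model to simulate
    threshold-tracking nerve-excitability-test (NET) batteries
    (strength-duration, threshold electrotonus, current-threshold,
    recovery cycle).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
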