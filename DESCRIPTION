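Package: epileptornet
Title: Seizure Spread in Delay-Coupled Stochastic Epileptor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and linear-stability analysis of focal-seizure spread
    on structural brain networks modelled as delay-coupled stochastic
    Epileptor neural-mass systems. Provides a stochastic Heun integrator for
    the full six-variable Epileptor and its two-variable reduction, a seizure
    protocol with epileptogenic-zone activation and postictal uncoupling,
    coarse-graining of trajectories into binary recruitment outcomes, phase
    diagrams of spread size over excitability and global coupling strength,
    and a two-Jacobian fixed-point stability method that predicts the phase
    diagram and the temporal order of node recruitment from the leading
    eigenvector. Includes a synthetic connectome generator with heavy-tailed
    weights and geometric tract lengths for fully reproducible studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
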