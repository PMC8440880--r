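Package: massnet
Title: Neural Mass Network Models of Seizure-Like Recruitment on Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of seizure-like propagation in whole-brain
    networks of next-generation neural mass models. Each brain region is an
    exact mean-field reduction of a heterogeneous quadratic integrate-and-fire
    (QIF) population with Lorentzian-distributed excitabilities, coupled
    through a structural connectome. The package provides the two-variable
    (rate, mean voltage) model and a finite-size QIF simulator serving as a
    microscopic oracle, fixed-point and bifurcation analysis, adiabatic
    up/down sweep protocols, stimulation and recruitment experiments,
    per-region excitability threshold scans, weighted graph metrics,
    spectrogram estimation of simulated field potentials, and evaluation of
    epileptogenic-zone/propagation-zone hypotheses, together with a seeded
    synthetic-connectome generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
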