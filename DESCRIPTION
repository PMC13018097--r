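Package: oncowave
Title: Hybrid Stochastic and Continuum Models of Oncolytic Virotherapy
Version: 0.1.0
Authors@R:
    person("Oncowave", "Developers", email = "oncowave@example.org",
           role = c("aut", "cre"))
Description: Simulates the spatial spread of an oncolytic virus through a
    growing tumour with explicit viral dynamics. Provides a stochastic hybrid
    lattice agent-based simulator (integer cell counts coupled to a continuous
    viral concentration), explicit finite-difference solvers for the matching
    reaction-diffusion and pressure-driven cross-diffusion systems (with and
    without an explicit virus equation), non-spatial ODE models with
    equilibrium, stability and Hopf-bifurcation analysis, linear-spreading-speed
    theory for infection invasion fronts, empirical front tracking, and
    tumour/infection control probabilities (discrete over stochastic ensembles
    and Poissonian from continuum solutions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
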