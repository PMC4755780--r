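Package: swarmevol
Title: Evolution of Collective Sensing in Self-Propelled Agent Swarms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of the evolution of collective sensing in
    mobile animal groups. Self-propelled agents on a periodic two-dimensional
    domain interact through a k-nearest-neighbour attraction-repulsion social
    force and modulate their speed in response to a dynamic multi-peak
    resource landscape; heritable behavioural traits (baseline speed,
    environmental sensitivity, interaction range) evolve under
    fitness-proportional selection. The package provides the particle
    dynamics, the resource environment with drifting, diffusing and
    relocating Gaussian peaks (including a depletion variant), the
    generational evolutionary loop with an asocial control and invasion
    experiments, and analysis protocols for collective-state transitions:
    hysteresis and phase sweeps of the mean distance to the ten nearest
    neighbours, potential-energy order parameters, Kullback-Leibler
    divergence between agent density and the resource distribution, arrival
    curves with linear and exponential model fits, and group-to-peak size
    matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    arrow,
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
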