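Package: floquetad
Title: Evolutionary Invasion Analysis on Ecological Limit Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Eco-evolutionary invasion analysis for host-parasite ODE models
    whose ecological attractors are limit cycles, arising either from seasonal
    forcing of competition or births, or intrinsically from free-living
    parasite stages. Computes the invasion fitness of rare mutant hosts as the
    dominant Floquet exponent of the linearized mutant subsystem on the
    resident attractor, via numerically assembled monodromy matrices. Locates
    and classifies evolutionarily singular strategies (continuously stable
    strategies, branching points), builds pairwise invasion plots, tracks
    singular strategies across parameter sweeps, and cross-validates the
    invasion analysis with direct multi-strain simulation of the evolutionary
    process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
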