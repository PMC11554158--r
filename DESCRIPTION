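Package: hipposim
Title: Center-Based Multicellular Simulation of Hippo-YAP/TAZ Contact Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-dimensional center-based (off-lattice) multicellular
    simulator in which a softcore Lennard-Jones (12-6) potential with linear
    friction drives cell mechanics via velocity-Verlet integration, coupled to
    a per-cell linear reaction network for Hippo-YAP/TAZ signaling. The local
    packing fraction of each cell feeds the density-dependent phosphorylation
    of YAP/TAZ; nuclear YAP/TAZ above a threshold permits growth and
    volume-conserving division, below it the cell cycle arrests. Normal and
    cancer tissue presets differ only in initial YAP/TAZ levels (twofold),
    reproducing contact inhibition of proliferation and its evasion. Includes
    exact eigendecomposition propagation of the reaction system, analytic
    steady states and critical arrest densities, population statistics,
    growth-curve analysis, and plain-text trajectory output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
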