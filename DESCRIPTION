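Package: spindlemc
Title: Monte Carlo Simulation of Spindle-Shaped Cell Monolayers on Ridged
    Substrates with Topological Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based Metropolis Monte Carlo model of proliferating
    fibroblast monolayers on micro-ridged substrates that impose +1 and -1
    nematic topological defects. Cells are deformable self-propelled ellipses
    with quartic shape energies, a modified Gay-Berne pair potential with an
    elliptical interaction cutoff, a ridge-overlap penalty sampled on feeler
    ellipses, polarity feedback with stochastic reversals, and shape-dependent
    cell division. Includes the accompanying quantification suite: alignment
    RMSD against the defect-imposed orientation field, radial density and
    aspect-ratio profiles, velocity-direction histograms, ridge-occupancy
    ratios and speed time series, plus configuration, trajectory persistence
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
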