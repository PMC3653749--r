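Package: spnperturb
Title: Signalling Petri Net Simulation and In Silico Perturbation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Token-flow simulation of bipartite species/reaction signalling
    networks in the Signalling Petri Net style, with seed-centred subnetwork
    extraction (strongly connected core plus weakly connected augmentation),
    stochastic ensemble simulation of control and perturbed scenarios
    (knockdown and overexpression of a seed molecule), and identification of
    species whose equilibrium token level changes significantly via a
    two-sample t statistic at the final time point. Includes a synthetic
    network generator with planted ground truth, GraphML import/export, and
    an end-to-end pipeline driver producing tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
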