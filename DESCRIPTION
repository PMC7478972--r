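Package: halotaxis
Title: Swimming Statistics and Chemotaxis Simulation for Slow Helical
    Microswimmers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing three-dimensional swimming trajectories of
    slow run-and-reverse microswimmers such as halophilic archaea. Provides a
    synthetic trajectory generator with helical kinematics, rotational
    diffusion and localization noise; spline smoothing, motility
    classification, reversal detection and run segmentation; direction
    autocorrelation analysis with a helical-plus-Brownian model for rotational
    diffusivity, helix pitch angle and angular frequency; a sector-based
    chemotaxis assay with fractional drift estimation; and a Brownian dynamics
    simulator of chemotactic swimmers with an adaptive linear-response
    reversal-rate model, reporting drift velocity, mean-squared displacement
    and chemotactic efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
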