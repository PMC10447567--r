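Package: biofilmHP
Title: One-Dimensional Biofilm Dynamics Under Continuous Hydrogen
    Peroxide Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a one-dimensional biofilm growing in a continuous
    stirred-tank reactor and challenged with hydrogen peroxide. Couples
    Monod growth of live biomass, first-order disinfection, catalase-type
    neutralization of the biocide by live and dead cells, solute
    diffusion-reaction through the film, growth-driven particulate
    advection, and quadratic surface detachment on a moving-thickness
    domain solved by the method of lines with a stiff integrator.
    Provides scenario runners for untreated, continuously dosed, pulse
    dosed, neutralization-knockout and nutrient-modulation cases, dose
    and glucose sweeps, bisection searches for eradication and
    dose-response thresholds, and metrics such as areal biomass, log
    reduction in viable cells, live-cell volume fraction and solute
    penetration depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
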