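Package: territoria
Title: Territorial Random Walks and Home-Range Estimation from Movement Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of animal movement in confined space:
    a scent-mediated territorial random-walk lattice simulator with finite
    active scent time, closed-form and numerical estimators of home-range
    size from the saturation of mark-recapture mean-square displacement
    observed through a finite trapping grid, analytic mean-square
    displacement of persistent walkers inside fixed rectangular territories,
    spring-tethered territory-boundary dynamics, and trajectory-level
    inference including multifractal Hurst-exponent estimation, steady-state
    potential fitting and maximum-likelihood parameter estimation with
    bootstrap intervals. Seeded synthetic-data generators (tethered
    Smoluchowski walkers, mark-recapture sampling windows, persistent walks
    in boxes and circular arenas, anomalous diffusion) are included for
    validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
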