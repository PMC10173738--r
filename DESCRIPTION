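Package: mtcentering
Title: Stochastic Microtubule-Pushing Model of Nucleus Centering in Fission Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates interphase nucleus centering in fission yeast driven by
    microtubule polymerization forces against the cell tips, with Euler
    buckling, anisotropic slender-body drag, and gamma-distributed catastrophe
    times. Provides fidelity statistics for centering trajectories
    (reliability delta, robustness sigma_x, failure coefficient Phi, with
    moving-block bootstrap errors), grid-based Bayesian inference of
    catastrophe-time distributions with an informative Mal3-anchored prior,
    parameter-sweep drivers over cell length and microtubule number, and
    seeded synthetic-data generators for all tabular inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    optparse
Config/testthat/edition: 3
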