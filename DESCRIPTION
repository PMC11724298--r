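Package: overstretch
Title: Thermodynamics and Kinetics of the DNA B-to-S Overstretching
    Transition from Force Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for constant-velocity optical-tweezers
    stretch/release experiments on short DNA duplexes that hop between the
    B form and the overstretched S form. Detects the abrupt force jumps of
    individual B-to-S and S-to-B transitions on force-distance curves, fits
    the two elastic branches, and estimates the equilibrium transition
    force, transition extension, free energy (mean-work and Bennett
    acceptance-ratio estimators), the number of base pairs undergoing the
    transition and the per-base-pair free energy. Reconstructs
    force-dependent transition rates from survival analysis of dwell
    intervals, fits them to the Bell-Evans model to locate the transition
    state, estimates the per-base-pair barrier from the scaling of
    transition counts with duplex length, and rebuilds the zero-force free
    energy profile. A kinetic Monte Carlo generator emulates the
    experimental protocol so that every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
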