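Package: chemodegen
Title: Degeneration of Penicillin Production in Chemostat Cultures
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of strain degeneration in
    ethanol-limited chemostat cultivations of penicillin-producing
    Penicillium chrysogenum. Simulates mixed producer/non-producer
    populations through a batch phase followed by continuous cultivation,
    generates measurement-like concentration time series, estimates
    biomass-specific production and growth rates from such series via a
    dynamic product mass balance with polynomial smoothing, checks carbon,
    degree-of-reduction and precursor balance closure, performs
    pseudo-steady-state metabolic flux analysis on a bundled reduced
    stoichiometric network, computes redox-sensor and adenylate energy
    charge diagnostics, and infers the non-producing subpopulation
    fraction from degeneration profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
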