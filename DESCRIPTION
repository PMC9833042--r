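Package: rubiscotherm
Title: Temperature Acclimation of Rubisco Kinetics and Photosynthetic CO2 Assimilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how growth temperature reshapes Rubisco
    kinetics and leaf CO2 assimilation. Provides Arrhenius evaluation and
    fitting of Rubisco kinetic constants (kcatCO2, SC/O, KC, KO), derived
    quantities (the CO2 compensation point Gamma* and the apparent Michaelis
    constant KC at 21% O2), a Henry's-law bridge between dissolved (uM) and
    gas-phase (umol/mol) concentrations, a forward Farquhar-von
    Caemmerer-Berry assimilation model with finite mesophyll conductance,
    inverse estimation of gm, Vcmax and Jmax from A-Ci curves by a two-limb
    split fit with a transition-point criterion, Michaelis-Menten estimation
    of the in vivo apparent KC, and a seeded synthetic-data generator that
    emulates a 2 growth x 2 measurement temperature gas-exchange study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
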