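Package: stoverheat
Title: Microbial Heat and Dry Matter Loss in Aerated Corn Stover Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter dynamical model of microbial self-heating and
    organic-matter loss in laboratory-scale aerated corn stover storage
    reactors. Couples bi-phasic (diauxic) first-order substrate degradation
    kinetics, modulated by a cardinal temperature model with inflection and a
    Monod moisture factor, to a single-node thermal energy balance with
    conductive, convective and evaporative heat exchange. Provides an adaptive
    Dormand-Prince forward simulator, bounded Levenberg-Marquardt calibration
    of epistemic parameters against observed temperature and off-gas-derived
    substrate series, validation error metrics, and a seeded synthetic-data
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
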