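Package: biosorb
Title: Biosorption Kinetics and Isotherm Modelling for Dye Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dye-biosorption experiments with microbial
    biomass: optical-density calibration curves, removal and adsorption
    quantities, one-parameter pseudo-first-order (Lagergren) and Ho
    second-order kinetic fits, model comparison by the model selection
    criterion (MSC), through-origin linear (C-type) equilibrium isotherms,
    a radial-diffusion (cylindrical Bessel eigenmode) model that motivates
    the first-order rate law, and seeded synthetic-data generators that
    emulate the experimental designs so every stage is testable by
    Monte-Carlo parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
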