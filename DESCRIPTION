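Package: n2okin
Title: Gas Kinetics of Nitrous Oxide-Respiring Enrichments in Closed Vials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing headspace gas kinetics from robotized
    incubations of anaerobic digestates and soils in crimp-sealed serum
    vials. Converts measured headspace concentrations (O2, N2, N2O, NO,
    CO2, CH4) into true cumulative production and consumption by modelling
    Henry's-law gas-liquid partitioning and the helium back-fill dilution
    caused by robotic sampling; derives respiratory electron-flow and
    carbon-mineralization budgets; fits a two-population model (one
    exponentially growing, one declining) to N2-production rates to
    reconstruct the density and cell-specific electron flow of
    N2O-respiring bacteria; and computes the N2O emission index (I_N2O)
    with its T_40/T_100 nitrogen-recovery anchors. A seeded mechanistic
    simulator of enrichment vials and soil microcosms provides ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
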