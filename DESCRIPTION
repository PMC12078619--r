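Package: soluthermo
Title: Thermophysical Analysis of Drug-Excipient Aqueous Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Volumetric, viscometric and interfacial analysis of small-molecule
    drugs in aqueous surfactant media. Converts density series into apparent
    molar volumes, fits Masson's equation, derives apparent specific volumes
    with taste classification and electrostriction hydration numbers; fits the
    Jones-Dole equation for viscosity B-coefficients; locates the critical
    micelle concentration from surface-tension isotherms by a two-segment
    breakpoint fit and computes surface pressure, Gibbs surface excess, minimum
    molecular area and micellization/adsorption free energies. Includes
    instrument-realistic synthetic-data generators with known ground truth for
    end-to-end parameter-recovery testing, and transcribed reference tables for
    gabapentin in aqueous betaine, betaine-urea deep eutectic solvent and
    betaine octyl ester chloride ionic liquid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
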