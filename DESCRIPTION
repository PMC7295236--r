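Package: mwablate
Title: Coupled Electromagnetic-Bioheat-Cell-Death Simulation of Microwave
    Tumor Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale axisymmetric simulator of microwave tumor ablation.
    Solves the frequency-domain wave equation for a coaxial slot antenna (single
    or double slot), advances the Pennes bioheat equation with
    temperature-dependent dielectric and thermal properties, an evaporation
    enthalpy sink and a Robin boundary condition, integrates three-state
    (alive/vulnerable/dead) cell-death kinetics, and accumulates
    temperature-time-integral tissue-shrinkage diagnostics. Scenario drivers
    sweep tumor shape (sphere, prolate and oblate spheroids of equal volume),
    size, input power, frequency and antenna layout under a collateral-damage
    stopping rule, reporting ablation-zone axes and region-mean dead-cell
    fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
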