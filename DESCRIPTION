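Package: idaburden
Title: Health-Economic Simulation of Iron-Deficiency Anemia Burden in
    Young Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the lifetime health and economic burden of
    iron-deficiency anemia (IDA) in children aged 6-23 months, stratified
    by socioeconomic decile, and the impact of fortified infant cereal
    (FIC) consumption. Implements hemoglobin distribution machinery
    (altitude adjustment, anemia severity classification, counterfactual
    exposure-shift mixtures), a lagged consumption-to-hemoglobin
    dose-response, comparative risk assessment with discounted lifetime
    production losses and disability-adjusted life years (DALYs), policy
    scenario comparisons, Monte Carlo probabilistic sensitivity analysis,
    and a seeded synthetic child-level survey generator for fully
    self-contained runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
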