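Package: volkin
Title: Population Volume Kinetics of Intravenous Fluids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Volume-kinetic analysis of intravenous crystalloid and colloid
    fluids from hemoglobin-derived plasma dilution. Provides exact solutions
    of one- and two-volume linear kinetic models, an extracellular-water
    covariate on the baseline peripheral fluid space, nonlinear mixed-effects
    estimation with a first-order conditional (FOCE-with-interaction style)
    approximate likelihood, likelihood-ratio model and covariate selection,
    nonparametric bootstrap and predictive-check validation, deterministic
    fluid-comparison simulation, and a synthetic crossover-trial generator
    for end-to-end testing without volunteer data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    numDeriv,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
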