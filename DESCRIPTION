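Package: refcorrect
Title: Correcting Diagnostic Test Accuracy for an Imperfect Reference Standard
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form correction methods (Gart-Buck, Staquet, Brenner) that
    estimate the sensitivity and specificity of a binary index test from a 2x2
    contingency table when the reference standard is imperfect with known
    accuracy, together with Wilson score confidence intervals, a multinomial
    simulation engine with fixed-effects conditional-dependence modelling,
    Monte-Carlo performance evaluation (bias, empirical SE, MSE) over sample
    size and prevalence sweeps, packaged clinical case studies, and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
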