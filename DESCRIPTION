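Package: ehsra
Title: Environmental Heat Strain Risk Assessment Index
Version: 1.0.0
Authors@R:
    person("EHSRA", "Maintainers", email = "maintainers@ehsra.dev", role = c("aut", "cre"))
Description: Computes the Environmental Heat Strain Risk Assessment (EHSRA)
    index, a weighted sum of six min-max normalized thermal and workload
    variables (dry, natural wet-bulb and globe temperatures, air velocity,
    total metabolism, clothing insulation) with four ROC-derived risk bands,
    and implements the full development pipeline behind it: a one-latent-factor
    path model fitted by maximum likelihood to a covariance matrix with
    direct/indirect effect decomposition and goodness-of-fit indices, ROC
    optimal cut-point selection against tympanic-temperature thresholds,
    regression validation with a closed-form R-squared oracle, and a
    multivariate-normal synthetic cohort generator calibrated to published
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
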