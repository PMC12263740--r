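Package: nlmrbias
Title: Bias Diagnostics for Stratified Non-Linear Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and diagnostic tools for evaluating bias in stratified
    ("non-linear") Mendelian randomization. Implements the residual and
    doubly-ranked stratification methods with within-stratum Wald-ratio
    estimation, Monte Carlo scenario drivers for gene-by-environment
    interaction designs, performance measures (stratum-wise mean squared
    error, Cochran's Q heterogeneity detection rate, confidence-interval
    coverage), counterfactual rank-preservation diagnostics for a catalogue
    of genotype-exposure models, and a semi-empirical falsification test
    that grafts simulated confounding onto a measured exposure and polygenic
    score to expose violations of the constant-genetic-effect and
    rank-preserving assumptions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
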