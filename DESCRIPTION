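Package: anchorbn
Title: Bayesian Networks with Genetic Anchors Versus Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based comparison of score-based Bayesian network
    structure learning with genetic anchor constraints against Mendelian
    randomization (two-stage least squares, with and without first-stage
    uncertainty correction) and the MR Steiger directionality procedure.
    Provides generators for three families of synthetic data sets
    (quantitative traits with weak or strong confounding, discrete binary
    traits, and a highly pleiotropic SNP-metabolite-outcome design),
    decomposable BIC scoring for Gaussian and multinomial nodes,
    hill-climbing and exhaustive structure search under blacklist and
    whitelist constraints, nonparametric bootstrap model averaging with edge
    strength and direction probabilities, allele-score construction, and a
    replicate-level evaluation harness computing power, type-I error and
    ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
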