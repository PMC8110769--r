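Package: serialbias
Title: Serial Dependence and Representational Momentum in Orientation Adjustment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-trial orientation adjustment errors
    in sequential psychophysics designs. Quantifies repulsive adaptation,
    forward displacement under implied rotation (representational momentum),
    and attractive serial dependence toward previous reports with a
    derivative-of-Gaussian bias model fitted by constrained least squares,
    stratified bootstrap and permutation inference on the amplitude,
    a model-free positive-versus-negative delta index, and a regression
    dominance analysis of stimulus history against report history. Includes
    generators for the blocked rotational/random sequence designs and a
    configurable synthetic observer so that every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
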