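Package: gklreg
Title: Ridge-Type Shrinkage Estimation for the Gamma Regression Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Maximum likelihood and biased (shrinkage) estimation for gamma
    regression with a log-linear mean under multicollinearity. Implements the
    gamma ridge estimator, the gamma Liu estimator and the single-parameter
    Kibria-Lukman ridge-type estimator, together with their analytic matrix
    mean squared error (MMSE) risk formulas, data-driven biasing-parameter
    selectors, sufficient-condition superiority checks, collinearity
    diagnostics, and a Monte-Carlo engine for comparing the estimators'
    empirical mean squared error over collinear designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
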