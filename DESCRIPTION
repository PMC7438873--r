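Package: longdcm
Title: Multivariate Longitudinal Diagnostic Classification Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measurement of growth in binary latent skills ("attributes") with a
    multivariate longitudinal diagnostic classification model: the log-linear
    cognitive diagnosis model (LCDM) measures attribute mastery at each
    occasion, and a generalized multivariate logistic growth-curve model with
    correlated person-level random intercepts and slopes describes change in
    mastery over continuous (possibly person-specific) time. Includes a
    synthetic-data generator for factorial simulation designs, Bayesian
    estimation by a vectorized Metropolis-within-Gibbs sampler, Gelman-Rubin
    convergence diagnostics, classification-accuracy summaries (correct
    classification rates, Cohen's kappa), parameter-recovery metrics (bias,
    MSE), and factorial-ANOVA effect sizes (partial eta squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
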