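Package: waldmix
Title: Shifted-Wald Response-Time Models with Across-Trial Drift Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Density, random generation, and Bayesian estimation for the
    shifted-Wald (shifted inverse Gaussian) response-time model for
    one-choice reaction-time tasks, extended with across-trial variability
    in the drift rate. Provides the closed-form marginal density when
    trial-level drift rates follow a zero-truncated normal distribution and
    a quadrature-based marginal when they follow a gamma distribution,
    exact samplers for all model distributions, adaptive-Metropolis MCMC
    fitting with Gelman-Rubin convergence monitoring and automatic chain
    extension, parameter-recovery study orchestration, and quantile-based
    goodness-of-fit assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
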