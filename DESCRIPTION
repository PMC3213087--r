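Package: geobma
Title: Bayesian Model Averaging for Geostatistical Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous covariate selection and parameter inference for
    geostatistical regression models via a partial-analytic reversible-jump
    Markov chain Monte Carlo (PARJ) sampler.  Supports Gaussian responses and
    Poisson spatial generalized linear mixed models with a latent Gaussian
    field, anisotropic exponential, spherical, or Matern correlation with
    nugget, Bernoulli-product model priors with per-covariate prior inclusion
    probabilities, and Langevin-Hastings (MALA) latent-field updates.  Chain
    output is summarised as posterior model probabilities, posterior inclusion
    probabilities, model-averaged coefficient mixtures, highest-posterior-density
    intervals, and coefficient-ratio functionals, with tidy() / glance() /
    autoplot() methods and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
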