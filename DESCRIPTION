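Package: lifecourse
Title: Life-Course Models of Psychosocial Adversity and Epigenetic Age
    Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the life-course effect of psychosocial
    adversity on epigenetic age acceleration and for identifying the most
    compatible life-course hypothesis (critical period, sensitive period,
    accumulation, or pathway). Implements a marginal-structural Bayesian
    relevant life-course model: inverse-probability-of-treatment weights
    composed with survey sampling weights, a weighted finite population
    Bayesian bootstrap (Polya posterior), a simplex-constrained Bayesian
    linear model for period weights fitted by a Gibbs/Metropolis sampler,
    weighting-based causal mediation with randomized interventional
    analogues of natural direct and indirect effects, and Euclidean-distance
    compatibility scoring against reference life-course vectors. Includes a
    synthetic cohort generator with known ground truth for validation.
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
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
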