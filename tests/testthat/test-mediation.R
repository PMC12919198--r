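toy_mediation_data <- function(n, seed, theta2 = 2, p0 = 0.4, p1 = 0.6) {
  set.seed(seed)
  a <- rbinom(n, 1, 0.5)
  m <- rbinom(n, 1, ifelse(a == 1, p1, p0))
  y <- 1 + 0.5 * a + theta2 * m + rnorm(n, 0, 0.5)
  list(data = tibble::tibble(.y = y, child_score = a, adult_score = m,
                             outcome = y),
       w = rep(1, n))
}

test_that("binary-mediator toy matches the product-of-coefficients closed form", {
  toy <- toy_mediation_data(10000, seed = 1)
  mm <- fit_mediator_model(toy$data, toy$w)
  om <- fit_outcome_model(toy$data, toy$w, interaction = FALSE)
  eff <- estimate_effects(mm, om, a = 1, a_star = 0)

  # closed form: theta2 * (P(M=1|a=1) - P(M=1|a=0)) = 2 * 0.2 = 0.4
  expect_lt(abs(eff[["rNIE"]] - 0.4), 0.02)

  theta2_hat <- coef(om$fit)[[".m"]]
  p1_hat <- predict(mm$fit, newdata = data.frame(.a = 1), type = "probs")
  p0_hat <- predict(mm$fit, newdata = data.frame(.a = 0), type = "probs")
  expect_equal(eff[["rNIE"]], theta2_hat * (p1_hat - p0_hat),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("total effect decomposes exactly into direct plus indirect", {
  toy <- toy_mediation_data(2000, seed = 2)
  mm <- fit_mediator_model(toy$data, toy$w)
  for (inter in c(TRUE, FALSE)) {
    om <- fit_outcome_model(toy$data, toy$w, interaction = inter)
    eff <- estimate_effects(mm, om, a = 1, a_star = 0)
    expect_identical(eff[["TE"]], eff[["rNDE"]] + eff[["rNIE"]])
  }
  cohort <- generate_cohort(cohort_config(n_subjects = 800), seed = 3)
  med <- mediate_lifecourse(cohort, n_boot = 0)
  expect_identical(med$estimates[["TE"]],
                   med$estimates[["rNDE"]] + med$estimates[["rNIE"]])
})

test_that("severing the childhood-to-adulthood path nullifies the indirect effect", {
  cohort <- generate_cohort(scenario_config("accumulation", 5000), seed = 4)
  med <- mediate_lifecourse(cohort, n_boot = 0)
  expect_lt(abs(med$estimates[["rNIE"]]), 0.05)
})

test_that("a genuine pathway yields a clearly positive indirect effect", {
  cohort <- generate_cohort(scenario_config("pathway", 3000), seed = 5)
  med <- mediate_lifecourse(cohort, n_boot = 60, seed = 6)
  td <- tidy(med)
  rnie <- td[td$term == "rNIE", ]
  expect_gt(rnie$estimate, 0.1)
  expect_gt(rnie$conf.low, 0)
  expect_true(all(td$conf.low <= td$conf.high))
})

test_that("identical exposure and reference levels are rejected", {
  toy <- toy_mediation_data(500, seed = 7)
  mm <- fit_mediator_model(toy$data, toy$w)
  om <- fit_outcome_model(toy$data, toy$w)
  expect_error(estimate_effects(mm, om, a = 1, a_star = 1), "differ")
})

test_that("degenerate bootstrap resamples are skipped with a warning", {
  cohort <- generate_cohort(cohort_config(n_subjects = 250), seed = 8)
  # make the exposure nearly constant so many resamples are degenerate
  cohort$child_substance <- 0L
  cohort$child_deprivation <- 0L
  cohort$child_abuse <- c(1L, 1L, rep(0L, 248))
  cohort$child_score <- cumulative_score(cohort$child_substance,
                                         cohort$child_deprivation,
                                         cohort$child_abuse)
  warnings <- testthat::capture_warnings(
    med <- mediate_lifecourse(cohort, n_boot = 40, seed = 9))
  expect_true(any(grepl("skipped", warnings)))
  expect_gt(med$n_skipped, 0)
})
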