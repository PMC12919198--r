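test_that("IPTW on the saturated one-confounder toy matches hand computation", {
  cohort <- confounded_toy()
  # subject 1 has L = 1, A = 1: P(A=1|L=1) = 0.8, marginal P(A=1) = 0.5
  unstab <- suppressWarnings(
    compute_iptw(cohort, exposure = "substance", stabilized = FALSE))
  expect_equal(unstab$iptw_child[1], 1.25, tolerance = 1e-6)

  stab <- suppressWarnings(
    compute_iptw(cohort, exposure = "substance", stabilized = TRUE))
  expect_equal(stab$iptw_child[1], 0.625, tolerance = 1e-6)
  # unexposed subject with L = 1: unstabilized 1/0.2 = 5, stabilized 0.5/0.2
  expect_equal(unstab$iptw_child[9], 5, tolerance = 1e-6)
  expect_equal(stab$iptw_child[9], 2.5, tolerance = 1e-6)
})

test_that("weight composition is the elementwise product", {
  expect_equal(combine_weights(2, 1.5), 3)
  expect_equal(combine_weights(c(1, 2), c(3, 0.5)), c(3, 1))
  expect_error(combine_weights(0, 1), "positive")
  expect_error(combine_weights(1, -2), "positive")
})

test_that("diagnostics report the Kish effective sample size", {
  d1 <- weight_diagnostics(rep(1, 970))
  expect_equal(d1$n_eff, 970)
  d2 <- weight_diagnostics(c(1, 1, 2))
  expect_equal(d2$n_eff, 16 / 6, tolerance = 1e-12)
  expect_equal(d2$mean, 4 / 3)
})

test_that("truncation clips at the requested percentiles", {
  w <- c(rep(1, 98), 0.01, 50)
  wt <- truncate_weights(w, lower = 0.01, upper = 0.99)
  expect_equal(max(wt), unname(quantile(w, 0.99)))
  expect_equal(min(wt), unname(quantile(w, 0.01)))
  expect_true(all(wt >= min(wt) & wt <= max(wt)))
})

test_that("stabilized total IPTW has mean near one on a confounded cohort", {
  cohort <- generate_cohort(cohort_config(n_subjects = 2000), seed = 21)
  w <- compute_iptw(cohort)
  expect_lt(abs(mean(w$iptw_total) - 1), 0.05)
  expect_true(all(is.finite(w$final_weight) & w$final_weight > 0))
})

test_that("a generator without confounding yields IPTW near one everywhere", {
  cfg <- cohort_config(
    n_subjects = 2000,
    confounder_effects = c(sex = 0, age = 0, parental_education = 0,
                           nativity = 0),
    intermediate_child_effect = 0,
    intermediate_adult_effects = c(own_education = 0, household_income = 0))
  cohort <- generate_cohort(cfg, seed = 22)
  w <- compute_iptw(cohort)
  # denominators are fitted, so deviations reflect estimation noise; at the
  # rare score levels the multiplicative noise is largest, so the check is
  # on the bulk of the distribution, not the extremes
  expect_lt(abs(mean(w$iptw_total) - 1), 0.02)
  expect_lt(median(abs(w$iptw_total - 1)), 0.1)
  expect_lt(unname(quantile(abs(w$iptw_total - 1), 0.95)), 0.3)
})

test_that("weighted regression with final weights recovers the marginal effects", {
  cfg <- cohort_config(n_subjects = 5000, truth_delta = 1,
                       truth_w_childhood = 0.7, residual_sd = 2)
  cohort <- generate_cohort(cfg, seed = 23)
  w <- compute_iptw(cohort)
  fit <- lm(outcome ~ child_score + adult_score, data = cohort,
            weights = w$final_weight)
  expect_lt(abs(coef(fit)[["child_score"]] - 0.7), 0.1)
  expect_lt(abs(coef(fit)[["adult_score"]] - 0.3), 0.1)
})

test_that("sensitivity covariate sets enter the exposure models", {
  cohort <- generate_cohort(cohort_config(n_subjects = 400), seed = 24)
  for (cs in c("base", "base+cells", "base+smoking")) {
    w <- compute_iptw(cohort, covariate_set = cs)
    expect_identical(attr(w, "covariate_set"), cs)
    expect_true(all(w$iptw_total > 0))
  }
  stripped <- cohort[setdiff(names(cohort), "smoking")]
  expect_error(compute_iptw(stripped, covariate_set = "base+smoking"),
               "smoking")
})

test_that("missing values are rejected rather than imputed", {
  cohort <- generate_cohort(cohort_config(n_subjects = 100), seed = 25)
  cohort$child_substance[3] <- NA
  expect_error(validate_cohort(cohort), "child_substance")
})
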