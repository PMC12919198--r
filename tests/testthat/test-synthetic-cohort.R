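test_that("cumulative scores and abuse pooling follow the coding rules", {
  expect_identical(cumulative_score(0, 0, 0), 0L)
  expect_identical(cumulative_score(1, 1, 1), 3L)
  expect_identical(cumulative_score(1, 0, 1), 2L)
  expect_identical(cumulative_score(c(1, 0), c(1, 1), c(0, 0)), c(2L, 1L))
  expect_error(cumulative_score(2, 0, 0), "0/1")
  expect_error(cumulative_score(NA, 0, 0), "0/1")

  expect_identical(pool_abuse(0, 0), 0L)
  expect_identical(pool_abuse(1, 0), 1L)
  expect_identical(pool_abuse(1, 1), 1L)
  expect_identical(pool_abuse(c(0, 0, 1), c(0, 1, 1)), c(0L, 1L, 1L))
  expect_error(pool_abuse(0.5, 0), "0/1")
})

test_that("generated cohorts satisfy the schema invariants", {
  cohort <- generate_cohort(cohort_config(n_subjects = 500), seed = 11)
  expect_silent(validate_cohort(cohort))
  expect_true(all(cohort$child_score ==
                    cohort$child_substance + cohort$child_deprivation +
                    cohort$child_abuse))
  expect_true(all(cohort$child_score %in% 0:3))
  expect_true(all(cohort$sampling_weight > 0))
  cells <- as.matrix(cohort[, c("cell_neu", "cell_cd4t", "cell_cd8t",
                                "cell_bcell", "cell_nk", "cell_mono")])
  expect_true(all(abs(rowSums(cells) - 1) < 1e-6))
})

test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(cohort_config(n_subjects = 300), seed = 42)
  b <- generate_cohort(cohort_config(n_subjects = 300), seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_subjects = 300), seed = 43)
  expect_false(identical(a$outcome, c$outcome))
})

test_that("realized prevalences hit configured targets (deprivation 54.2% child, 52.0% adult)", {
  cohort <- generate_cohort(cohort_config(n_subjects = 10000), seed = 7)
  expect_lt(abs(mean(cohort$child_deprivation) - 0.542), 0.02)
  expect_lt(abs(mean(cohort$adult_deprivation) - 0.520), 0.02)
})

test_that("pace-of-aging outcome calibrates to mean 1.08, SD 0.12", {
  cohort <- generate_cohort(
    cohort_config(n_subjects = 10000, outcome_kind = "DunedinPACE"),
    seed = 19)
  expect_lt(abs(mean(cohort$outcome) - 1.08), 0.01)
  expect_lt(abs(sd(cohort$outcome) - 0.12), 0.01)
})

test_that("zero carryover makes childhood and adulthood scores conditionally independent", {
  cfg <- cohort_config(
    n_subjects = 10000,
    carryover_strength = c(substance = 0, deprivation = 0, abuse = 0),
    intermediate_child_effect = 0,
    confounder_effects = c(sex = 0, age = 0, parental_education = 0,
                           nativity = 0))
  cohort <- generate_cohort(cfg, seed = 5)
  expect_lt(abs(cor(cohort$child_score, cohort$adult_score)), 0.03)
})

test_that("regression on the generated outcome recovers the period effects", {
  cfg <- cohort_config(n_subjects = 50000, truth_delta = 1,
                       truth_w_childhood = 0.7, residual_sd = 2)
  cohort <- generate_cohort(cfg, seed = 3)
  fit <- lm(outcome ~ child_score + adult_score + sex + age +
              parental_education + nativity, data = cohort)
  expect_lt(abs(coef(fit)[["child_score"]] - 0.7), 0.05)
  expect_lt(abs(coef(fit)[["adult_score"]] - 0.3), 0.05)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(residual_sd = -1), "residual_sd")
  expect_error(cohort_config(truth_w_childhood = 1.3), "truth_w_childhood")
  expect_error(
    cohort_config(prevalence = list(
      child = c(substance = 1.2, deprivation = 0.5, abuse = 0.2),
      adult = c(substance = 0.2, deprivation = 0.5, abuse = 0.1))),
    "prevalence")
})
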