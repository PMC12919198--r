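fake_mediation <- function(rnie_lo, rnie_hi, exposure = "cumulative",
                           outcome = "outcome") {
  structure(list(
    estimates = c(TE = 0.4, rNDE = 0.2, rNIE = mean(c(rnie_lo, rnie_hi))),
    ci = tibble::tibble(term = c("TE", "rNDE", "rNIE"),
                        conf.low = c(0, 0, rnie_lo),
                        conf.high = c(1, 1, rnie_hi)),
    contrast = c(a = 1, a_star = 0), interaction = TRUE,
    n_boot = 100L, n_skipped = 0L,
    exposure = exposure, mediator = exposure, outcome = outcome,
    boot = NULL
  ), class = "lc_mediation")
}

test_that("the reference set spans the five life-course hypotheses on the simplex", {
  refs <- lifecourse_references()
  expect_setequal(refs$name, c("accumulation", "critical_childhood",
                               "critical_adulthood", "sensitive_childhood",
                               "sensitive_adulthood"))
  expect_equal(refs$ref_child + refs$ref_adult, rep(1, 5))
  expect_equal(refs$ref_child[refs$name == "sensitive_childhood"], 0.67)
})

test_that("distances follow the simplex identity sqrt(2)|w - ref|", {
  expect_equal(euclidean_distance(0.5, "accumulation"), 0)
  expect_equal(euclidean_distance(1, "critical_adulthood"), sqrt(2))
  expect_equal(euclidean_distance(0.56, "accumulation"), sqrt(2) * 0.06,
               tolerance = 1e-10)
  expect_equal(round(euclidean_distance(0.56, "accumulation"), 5), 0.08485)

  set.seed(1)
  w <- runif(200)
  for (ref in lifecourse_references()$name) {
    rc <- lifecourse_references()$ref_child[lifecourse_references()$name == ref]
    expect_equal(euclidean_distance(w, ref), sqrt(2) * abs(w - rc),
                 tolerance = 1e-12)
  }
  expect_error(euclidean_distance(1.2, "accumulation"), "\\[0, 1\\]")
  expect_error(euclidean_distance(0.5, "nonsense"), "Unknown reference")
})

test_that("posterior distance tables find the nearest reference, ties to accumulation", {
  set.seed(2)
  ed <- ed_posterior(pmin(pmax(rnorm(5000, 0.5, 0.05), 0), 1))
  expect_identical(most_compatible(ed), "accumulation")
  expect_true(all(ed$estimate >= 0))
  expect_identical(ed$name[which.min(ed$estimate)], most_compatible(ed))

  ed_crit <- ed_posterior(rep(0.02, 100))
  expect_identical(most_compatible(ed_crit), "critical_adulthood")

  # equidistant between accumulation (0.5) and sensitive childhood (0.67)
  ed_tie <- ed_posterior(rep(0.585, 10))
  expect_identical(most_compatible(ed_tie), "accumulation")

  # invariance to draw order
  w <- runif(500)
  expect_equal(tibble::as_tibble(ed_posterior(w)),
               tibble::as_tibble(ed_posterior(rev(w))))
})

test_that("the verdict applies the pathway override then the smallest distance", {
  set.seed(3)
  fit_acc <- structure(list(
    draws = tibble::tibble(replicate_id = 1L, beta0 = 0,
                           delta = rep(0.9, 200),
                           w_childhood = rnorm(200, 0.5, 0.02),
                           sigma = 1),
    diagnostics = tibble::tibble(accept_rate = 0.4, ess_delta = 200,
                                 ess_w = 200, step_size = 1),
    n_replicates = 1L, n_draws = 200L,
    exposure = "cumulative", outcome = "outcome"), class = "msbrlm")

  v1 <- classify_lifecourse(fit_acc, fake_mediation(0.09, 0.37))
  expect_identical(v1$verdict, "pathway")
  expect_true(v1$pathway_supported)

  v2 <- classify_lifecourse(fit_acc, fake_mediation(-0.1, 0.2))
  expect_identical(v2$verdict, "accumulation")
  expect_identical(v2$weight_comparison, "w_childhood ~ w_adulthood")

  fit_crit <- fit_acc
  fit_crit$draws$w_childhood <- pmax(rnorm(200, 0.02, 0.01), 0)
  v3 <- classify_lifecourse(fit_crit, fake_mediation(-0.1, 0.2))
  expect_identical(v3$verdict, "critical_adulthood")
  expect_identical(v3$weight_comparison, "w_childhood < w_adulthood")

  expect_error(
    classify_lifecourse(fit_acc, fake_mediation(0, 1, exposure = "abuse")),
    "Exposure labels")
  expect_error(
    classify_lifecourse(fit_acc, fake_mediation(0, 1, outcome = "pace")),
    "Outcome labels")
})
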