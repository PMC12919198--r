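# Synthetic cohort generator
#
# Emulates the structure of a survey cohort of Hispanic/Latino adults with
# life-course psychosocial adversity and epigenetic-age outcomes. Generation
# follows the assumed causal ordering: baseline confounders -> childhood
# adversity -> intermediate confounders -> adulthood adversity -> outcome.
# Ground truth (beta0, delta, period weights, carryover) is recorded so every
# downstream estimator can be validated against it.

ADVERSITY_TYPES <- c("substance", "deprivation", "abuse")

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults follow
#' the observed composition of the motivating cohort of 970 Hispanic/Latino
#' adults: 61.4% female, 18.6% US-born, age mean 50.5 (SD 12.9, range 23-80),
#' material deprivation prevalence 54.2% in childhood and 52.0% in adulthood,
#' and an AgeAccelGrim outcome with SD near 3.9 years. The default life-course
#' truth places most of the adversity effect in adulthood (`truth_w_childhood
#' = 0.21`, i.e. an adulthood weight of 79%) with `truth_delta = 0.91` years
#' per unit weighted adversity.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param prevalence List with elements `child` and `adult`, each a named
#'   probability vector over `c("substance", "deprivation", "abuse")` giving
#'   the target marginal prevalence of each adversity type in that period.
#'   Intercepts of the exposure models are calibrated so the in-sample
#'   expected prevalence matches these targets exactly.
#' @param baseline List of baseline-confounder settings: `p_female`,
#'   `p_parent_educ` (parental education above high school), `p_usborn`,
#'   `age_mean`, `age_sd`, `age_min`, `age_max` (age is truncated normal).
#' @param intermediate List with `p_own_educ` and `p_income`, marginal targets
#'   for the two binary intermediate confounders (own education above high
#'   school; household income at or above $30,000).
#' @param confounder_effects Named log-odds effects of the baseline
#'   confounders on every adversity indicator: `sex`, `age` (per decade,
#'   centered), `parental_education`, `nativity`.
#' @param intermediate_child_effect Log-odds effect of the childhood
#'   cumulative score on each intermediate confounder.
#' @param intermediate_adult_effects Named log-odds effects of
#'   `own_education` and `household_income` on each adulthood adversity
#'   indicator.
#' @param carryover_strength Named log-odds effect of each childhood adversity
#'   indicator on its adulthood counterpart (the pathway mechanism). Zero
#'   severs the childhood-to-adulthood chain.
#' @param truth_beta0 Outcome intercept (outcome units).
#' @param truth_delta Life-course effect per unit weighted adversity.
#' @param truth_w_childhood Childhood period weight in `[0, 1]`; the adulthood
#'   weight is `1 - truth_w_childhood`.
#' @param residual_sd Outcome residual SD (must be positive).
#' @param outcome_kind `"AgeAccelGrim"` (years) or `"DunedinPACE"`
#'   (years/calendar year). Selecting DunedinPACE switches the unset outcome
#'   defaults to `truth_delta = 0.013`, `outcome_mean = 1.08`, `outcome_sd =
#'   0.12`, and small confounder-outcome effects.
#' @param outcome_mean,outcome_sd Optional calibration targets: when supplied,
#'   the intercept (and residual SD) are solved in-sample so the systematic
#'   mean (total SD) matches the target.
#' @param confounder_outcome_effects Named additive effects of the baseline
#'   confounders on the outcome (same names as `confounder_effects`; age per
#'   decade, centered).
#' @param intermediate_outcome_effects Named additive effects of
#'   `own_education` and `household_income` on the outcome. Zero by default so
#'   the generating truth stays transparent; set nonzero to create genuine
#'   intermediate confounding for mediation stress-tests.
#' @param sampling_weight_dispersion Log-scale SD of the log-normal survey
#'   sampling weights (unit mean).
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [scenario_config()]
#' @export
cohort_config <- function(n_subjects = 970,
                          prevalence = list(
                            child = c(substance = 0.35, deprivation = 0.542,
                                      abuse = 0.25),
                            adult = c(substance = 0.20, deprivation = 0.520,
                                      abuse = 0.10)),
                          baseline = list(p_female = 0.614,
                                          p_parent_educ = 0.553,
                                          p_usborn = 0.186,
                                          age_mean = 50.5, age_sd = 12.91,
                                          age_min = 23, age_max = 80),
                          intermediate = list(p_own_educ = 0.631,
                                              p_income = 0.279),
                          confounder_effects = c(sex = 0.3, age = 0.15,
                                                 parental_education = -0.4,
                                                 nativity = -0.3),
                          intermediate_child_effect = -0.35,
                          intermediate_adult_effects = c(own_education = -0.3,
                                                         household_income = -0.3),
                          carryover_strength = c(substance = 0.8,
                                                 deprivation = 0.8,
                                                 abuse = 0.8),
                          truth_beta0 = 0,
                          truth_delta = NULL,
                          truth_w_childhood = NULL,
                          residual_sd = NULL,
                          outcome_kind = c("AgeAccelGrim", "DunedinPACE"),
                          outcome_mean = NULL,
                          outcome_sd = NULL,
                          confounder_outcome_effects = NULL,
                          intermediate_outcome_effects = c(own_education = 0,
                                                           household_income = 0),
                          sampling_weight_dispersion = 0.5) {
  outcome_kind <- match.arg(outcome_kind)
  if (outcome_kind == "AgeAccelGrim") {
    truth_delta <- truth_delta %||% 0.91
    truth_w_childhood <- truth_w_childhood %||% 0.21
    residual_sd <- residual_sd %||% 3.8
    confounder_outcome_effects <- confounder_outcome_effects %||%
      c(sex = 0.5, age = 0, parental_education = -0.5, nativity = -0.5)
  } else {
    truth_delta <- truth_delta %||% 0.013
    truth_w_childhood <- truth_w_childhood %||% 0.49
    outcome_mean <- outcome_mean %||% 1.08
    outcome_sd <- outcome_sd %||% 0.12
    residual_sd <- residual_sd %||% 0.115
    confounder_outcome_effects <- confounder_outcome_effects %||%
      c(sex = 0.015, age = 0, parental_education = -0.015, nativity = -0.015)
  }

  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be at least 2.")
  }
  for (period in c("child", "adult")) {
    p <- prevalence[[period]]
    if (is.null(p) || !all(ADVERSITY_TYPES %in% names(p))) {
      abort(sprintf("`prevalence$%s` must name substance, deprivation, abuse.",
                    period))
    }
    assert_prob(p[ADVERSITY_TYPES], paste0("prevalence$", period))
  }
  assert_prob(c(baseline$p_female, baseline$p_parent_educ, baseline$p_usborn),
              "baseline probabilities")
  assert_prob(c(intermediate$p_own_educ, intermediate$p_income),
              "intermediate probabilities")
  if (!is.numeric(residual_sd) || residual_sd <= 0) {
    abort("`residual_sd` must be positive.")
  }
  if (!is.numeric(truth_w_childhood) || truth_w_childhood < 0 ||
      truth_w_childhood > 1) {
    abort("`truth_w_childhood` must lie in [0, 1].")
  }
  if (!is.numeric(sampling_weight_dispersion) ||
      sampling_weight_dispersion < 0) {
    abort("`sampling_weight_dispersion` must be nonnegative.")
  }
  if (!all(ADVERSITY_TYPES %in% names(carryover_strength))) {
    abort("`carryover_strength` must name substance, deprivation, abuse.")
  }

  structure(list(
    n_subjects = as.integer(n_subjects),
    prevalence = lapply(prevalence, function(p) p[ADVERSITY_TYPES]),
    baseline = baseline,
    intermediate = intermediate,
    confounder_effects = confounder_effects,
    intermediate_child_effect = intermediate_child_effect,
    intermediate_adult_effects = intermediate_adult_effects,
    carryover_strength = carryover_strength[ADVERSITY_TYPES],
    truth_beta0 = truth_beta0,
    truth_delta = truth_delta,
    truth_w_childhood = truth_w_childhood,
    residual_sd = residual_sd,
    outcome_kind = outcome_kind,
    outcome_mean = outcome_mean,
    outcome_sd = outcome_sd,
    confounder_outcome_effects = confounder_outcome_effects,
    intermediate_outcome_effects = intermediate_outcome_effects,
    sampling_weight_dispersion = sampling_weight_dispersion
  ), class = "cohort_config")
}

#' Preset generator configurations for life-course scenarios
#'
#' Convenience wrapper around [cohort_config()] encoding the two canonical
#' validation scenarios: `"accumulation"` (equal period weights and fully
#' independent exposure windows — no carryover and no childhood effect on the
#' intermediates — so the accumulation hypothesis is true)
#' and `"pathway"` (strong carryover of each childhood adversity into its
#' adulthood counterpart plus a substantial adulthood contribution, so the
#' indirect effect of childhood adversity is real). Both use `delta = 1`
#' with a unit residual SD: distinguishing the accumulation weight (0.5)
#' from the sensitive-period references (0.67/0.33) requires the period
#' weight's sampling error to be well below the 0.085 decision boundary,
#' which at n = 2000 holds for a unit SD but not for substantially noisier
#' outcomes.
#'
#' @param scenario `"accumulation"` or `"pathway"`.
#' @param n_subjects Cohort size.
#' @param ... Further overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
scenario_config <- function(scenario = c("accumulation", "pathway"),
                            n_subjects = 2000, ...) {
  scenario <- match.arg(scenario)
  if (scenario == "accumulation") {
    cohort_config(n_subjects = n_subjects, truth_delta = 1,
                  truth_w_childhood = 0.5, residual_sd = 1,
                  carryover_strength = c(substance = 0, deprivation = 0,
                                         abuse = 0),
                  intermediate_child_effect = 0, ...)
  } else {
    cohort_config(n_subjects = n_subjects, truth_delta = 1,
                  truth_w_childhood = 0.3, residual_sd = 1,
                  carryover_strength = c(substance = 2, deprivation = 2,
                                         abuse = 2), ...)
  }
}

# Solve the logistic intercept so mean(plogis(b0 + lp)) equals the target
# prevalence for the realized linear predictor lp.
calibrate_intercept <- function(lp, target) {
  uniroot(function(b0) mean(plogis(b0 + lp)) - target,
          lower = -30, upper = 30, tol = 1e-10)$root
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

rdirichlet1 <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}

#' Generate a synthetic life-course cohort
#'
#' Draws a cohort from the causal structure assumed by the analysis pipeline.
#' Baseline confounders are drawn first; each childhood adversity indicator is
#' Bernoulli with a logistic model in the baseline confounders; the two
#' intermediate confounders depend on the childhood cumulative score and
#' baseline confounders; each adulthood adversity indicator depends on
#' baseline confounders, intermediates, and its childhood counterpart (the
#' carryover/pathway term); finally the outcome is
#' `beta0 + delta * (w * child_score + (1 - w) * adult_score)` plus additive
#' confounder terms and Gaussian noise. Survey sampling weights are log-normal
#' with unit mean. All logistic intercepts are calibrated in-sample so
#' realized prevalences match the configured targets in expectation.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   cohorts.
#' @return A tibble with one row per subject (see [validate_cohort()] for the
#'   schema) carrying the generating truth as attribute `"truth"`, retrievable
#'   with [cohort_truth()].
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 200), seed = 1)
#' cohort_truth(cohort)$delta
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be built with cohort_config().")
  }
  set_seed_if(seed)
  n <- config$n_subjects
  bl <- config$baseline
  ce <- config$confounder_effects

  sex <- rbinom(n, 1, bl$p_female)
  age <- rtruncnorm(n, bl$age_mean, bl$age_sd, bl$age_min, bl$age_max)
  parental_education <- rbinom(n, 1, bl$p_parent_educ)
  nativity <- rbinom(n, 1, bl$p_usborn)
  age_c <- (age - bl$age_mean) / 10

  lp_conf <- ce[["sex"]] * sex + ce[["age"]] * age_c +
    ce[["parental_education"]] * parental_education +
    ce[["nativity"]] * nativity

  child <- matrix(0L, n, 3, dimnames = list(NULL, ADVERSITY_TYPES))
  for (type in ADVERSITY_TYPES) {
    b0 <- calibrate_intercept(lp_conf, config$prevalence$child[[type]])
    child[, type] <- rbinom(n, 1, plogis(b0 + lp_conf))
  }
  child_score <- as.integer(rowSums(child))

  lp_int <- lp_conf + config$intermediate_child_effect * child_score
  own_education <- rbinom(n, 1, plogis(
    calibrate_intercept(lp_int, config$intermediate$p_own_educ) + lp_int))
  household_income <- rbinom(n, 1, plogis(
    calibrate_intercept(lp_int, config$intermediate$p_income) + lp_int))

  iae <- config$intermediate_adult_effects
  lp_adult_base <- lp_conf + iae[["own_education"]] * own_education +
    iae[["household_income"]] * household_income
  adult <- matrix(0L, n, 3, dimnames = list(NULL, ADVERSITY_TYPES))
  for (type in ADVERSITY_TYPES) {
    lp <- lp_adult_base + config$carryover_strength[[type]] * child[, type]
    b0 <- calibrate_intercept(lp, config$prevalence$adult[[type]])
    adult[, type] <- rbinom(n, 1, plogis(b0 + lp))
  }
  adult_score <- as.integer(rowSums(adult))

  coe <- config$confounder_outcome_effects
  ioe <- config$intermediate_outcome_effects
  w <- config$truth_w_childhood
  weighted_score <- w * child_score + (1 - w) * adult_score
  systematic <- config$truth_delta * weighted_score +
    coe[["sex"]] * sex + coe[["age"]] * age_c +
    coe[["parental_education"]] * parental_education +
    coe[["nativity"]] * nativity +
    ioe[["own_education"]] * own_education +
    ioe[["household_income"]] * household_income

  beta0 <- config$truth_beta0
  if (!is.null(config$outcome_mean)) {
    beta0 <- config$outcome_mean - mean(systematic)
  }
  residual_sd <- config$residual_sd
  if (!is.null(config$outcome_sd)) {
    v <- config$outcome_sd^2 - var(systematic)
    if (v <= 0) {
      abort("`outcome_sd` target is smaller than the systematic SD; increase it or shrink the effects.")
    }
    residual_sd <- sqrt(v)
  }
  outcome <- beta0 + systematic + rnorm(n, 0, residual_sd)

  s <- config$sampling_weight_dispersion
  sampling_weight <- rlnorm(n, meanlog = -s^2 / 2, sdlog = s)

  smoking <- factor(sample(c("never", "former", "current"), n, replace = TRUE,
                           prob = c(0.618, 0.213, 0.169)),
                    levels = c("never", "former", "current"))
  cell_means <- c(cell_neu = 0.55, cell_cd4t = 0.16, cell_cd8t = 0.08,
                  cell_bcell = 0.06, cell_nk = 0.07, cell_mono = 0.08)
  cells <- rdirichlet1(n, cell_means * 120)
  colnames(cells) <- names(cell_means)

  cohort <- tibble::tibble(
    sex = sex, age = age, parental_education = parental_education,
    nativity = nativity,
    child_substance = child[, "substance"],
    child_deprivation = child[, "deprivation"],
    child_abuse = child[, "abuse"],
    child_score = child_score,
    own_education = own_education, household_income = household_income,
    adult_substance = adult[, "substance"],
    adult_deprivation = adult[, "deprivation"],
    adult_abuse = adult[, "abuse"],
    adult_score = adult_score,
    outcome = outcome,
    sampling_weight = sampling_weight,
    smoking = smoking
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(cells))

  truth <- list(
    beta0 = beta0,
    delta = config$truth_delta,
    w_childhood = w,
    w_adulthood = 1 - w,
    residual_sd = residual_sd,
    carryover_strength = config$carryover_strength,
    outcome_kind = config$outcome_kind,
    marginal_prevalence = list(child = colMeans(child),
                               adult = colMeans(adult))
  )
  attr(cohort, "truth") <- truth
  cohort
}

#' Retrieve the generating truth of a synthetic cohort
#'
#' @param cohort A tibble produced by [generate_cohort()].
#' @return The truth record: intercept, life-course effect `delta`, period
#'   weights (summing to one), residual SD, carryover strengths, and realized
#'   marginal prevalences.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) {
    abort("`cohort` carries no truth record; was it made by generate_cohort()?")
  }
  truth
}

#' Cumulative adversity score for one period
#'
#' Sums the three binary adversity indicators of a period into the cumulative
#' score used as the primary exposure (range 0-3).
#'
#' @param substance,deprivation,abuse Binary (0/1) vectors of equal length.
#' @return Integer vector in `{0, 1, 2, 3}`.
#' @examples
#' cumulative_score(1, 0, 1)
#' @export
cumulative_score <- function(substance, deprivation, abuse) {
  assert_binary(substance, "substance")
  assert_binary(deprivation, "deprivation")
  assert_binary(abuse, "abuse")
  as.integer(substance + deprivation + abuse)
}

#' Pool physical and sexual abuse into a single indicator
#'
#' Because abuse in adulthood is rare, physical and sexual abuse are combined
#' into one binary indicator per period: 1 if either occurred.
#'
#' @param physical,sexual Binary (0/1) vectors of equal length.
#' @return Binary integer vector.
#' @examples
#' pool_abuse(c(0, 1, 1), c(0, 0, 1))
#' @export
pool_abuse <- function(physical, sexual) {
  assert_binary(physical, "physical")
  assert_binary(sexual, "sexual")
  as.integer(physical | sexual)
}
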