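# Shared fixtures, built in code.

# Minimal schema-complete cohort from explicit pieces; every unspecified
# column is constant/benign so toy examples stay hand-checkable.
toy_cohort <- function(sex, child_substance, adult_substance = NULL,
                       outcome = NULL, sampling_weight = NULL) {
  n <- length(sex)
  adult_substance <- adult_substance %||% rep(c(0L, 1L), length.out = n)
  zeros <- rep(0L, n)
  tibble::tibble(
    sex = as.integer(sex),
    age = 50,
    parental_education = zeros,
    nativity = zeros,
    child_substance = as.integer(child_substance),
    child_deprivation = zeros,
    child_abuse = zeros,
    child_score = as.integer(child_substance),
    own_education = zeros,
    household_income = zeros,
    adult_substance = as.integer(adult_substance),
    adult_deprivation = zeros,
    adult_abuse = zeros,
    adult_score = as.integer(adult_substance),
    outcome = outcome %||% rnorm(n),
    sampling_weight = sampling_weight %||% rep(1, n)
  )
}

# The classic one-binary-confounder fixture: P(A=1|L=1)=0.8, P(A=1|L=0)=0.2,
# balanced L, so the marginal P(A=1)=0.5. Frequencies are exact by
# construction, making the saturated logistic fit reproduce them exactly.
confounded_toy <- function(reps = 1) {
  L <- rep(c(rep(1L, 10), rep(0L, 10)), reps)
  A <- rep(c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8)), reps)
  toy_cohort(sex = L, child_substance = A)
}

`%||%` <- rlang::`%||%`
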