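# Inverse-probability-of-treatment weights for the two time-ordered
# adversity exposures, composed with survey sampling weights into the final
# analysis weight. The childhood model conditions on baseline confounders
# only; the adulthood model additionally conditions on the intermediate
# confounders (own education, household income) and the childhood exposure,
# respecting the assumed time ordering.

BASE_CONFOUNDERS <- c("sex", "age", "parental_education", "nativity")
INTERMEDIATES <- c("own_education", "household_income")

exposure_cols <- function(exposure) {
  if (exposure == "cumulative") {
    c(child = "child_score", adult = "adult_score")
  } else {
    c(child = paste0("child_", exposure), adult = paste0("adult_", exposure))
  }
}

covariate_set_cols <- function(covariate_set) {
  extra <- switch(covariate_set,
                  "base" = character(),
                  # drop one cell proportion: the six sum to one
                  "base+cells" = setdiff(CELL_COLS, "cell_neu"),
                  "base+smoking" = "smoking",
                  abort("`covariate_set` must be base, base+cells, or base+smoking."))
  list(child = c(BASE_CONFOUNDERS, extra),
       adult = c(BASE_CONFOUNDERS, INTERMEDIATES, extra))
}

drop_constant <- function(cols, data) {
  keep <- vapply(cols, function(col) {
    x <- data[[col]]
    length(unique(x)) > 1L
  }, logical(1))
  cols[keep]
}

fit_prob_model <- function(response, covariates, data, label) {
  covariates <- drop_constant(covariates, data)
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f <- as.formula(paste(response, "~", rhs))
  binary <- all(data[[response]] %in% c(0, 1))
  fit <- tryCatch({
    if (binary) {
      glm(f, data = data, family = binomial())
    } else {
      dat <- data
      dat[[response]] <- factor(dat[[response]])
      nnet::multinom(f, data = dat, trace = FALSE, maxit = 500)
    }
  }, error = function(e) {
    abort(sprintf("Exposure model `%s` failed to fit: %s", label,
                  conditionMessage(e)))
  })
  if (!binary && !isTRUE(fit$convergence == 0)) {
    abort(sprintf("Exposure model `%s` did not converge.", label))
  }
  fit
}

# P(observed exposure level | covariates) per subject
observed_prob <- function(fit, data, observed) {
  if (inherits(fit, "multinom")) {
    pr <- predict(fit, newdata = data, type = "probs")
    levs <- fit$lev
    if (is.null(dim(pr))) {  # two-level response returns P(second level)
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- levs
    }
    idx <- match(as.character(observed), colnames(pr))
    if (anyNA(idx)) {
      abort("Observed exposure level absent from the fitted model's levels.")
    }
    pr[cbind(seq_len(nrow(pr)), idx)]
  } else {
    p <- predict(fit, newdata = data, type = "response")
    ifelse(observed == 1, p, 1 - p)
  }
}

#' Fit the exposure (propensity) models behind IPTW
#'
#' Fits the per-period probability models used to build inverse-probability
#' weights: a multinomial logistic model for the 4-level cumulative score or a
#' binomial logistic model for a single adversity type. The childhood model
#' conditions on the baseline confounders; the adulthood model additionally
#' conditions on the intermediate confounders and the childhood exposure.
#' Stabilization numerator models (marginal childhood exposure; adulthood
#' exposure given childhood exposure) are fitted alongside.
#'
#' @param cohort A validated cohort tibble.
#' @param exposure `"cumulative"` (default) or one of `"substance"`,
#'   `"deprivation"`, `"abuse"`.
#' @param covariate_set `"base"`, `"base+cells"` (adds five cell-type
#'   proportions), or `"base+smoking"` — the sensitivity configurations.
#' @return An object of class `lc_exposure_models`.
#' @export
fit_exposure_models <- function(cohort,
                                exposure = c("cumulative", "substance",
                                             "deprivation", "abuse"),
                                covariate_set = c("base", "base+cells",
                                                  "base+smoking")) {
  exposure <- match.arg(exposure)
  covariate_set <- match.arg(covariate_set)
  cohort <- validate_cohort(cohort)
  cols <- exposure_cols(exposure)
  covs <- covariate_set_cols(covariate_set)
  used <- unique(c(unname(cols), covs$child, covs$adult))
  missing_cols <- setdiff(used, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort lacks column(s) needed for covariate set `",
                 covariate_set, "`: ", paste(missing_cols, collapse = ", "),
                 "."))
  }

  structure(list(
    exposure = exposure,
    covariate_set = covariate_set,
    cols = cols,
    child_denom = fit_prob_model(cols[["child"]], covs$child, cohort,
                                 "childhood | confounders"),
    adult_denom = fit_prob_model(cols[["adult"]],
                                 c(covs$adult, cols[["child"]]), cohort,
                                 "adulthood | confounders + intermediates + childhood"),
    child_num = fit_prob_model(cols[["child"]], character(), cohort,
                               "childhood marginal"),
    adult_num = fit_prob_model(cols[["adult"]], cols[["child"]], cohort,
                               "adulthood | childhood")
  ), class = "lc_exposure_models")
}

#' Compute inverse-probability-of-treatment weights
#'
#' Builds per-subject IPTW for the childhood and adulthood exposures and
#' composes them with the survey sampling weight into the final analysis
#' weight (`final_weight = iptw_child * iptw_adult * sampling_weight`). With
#' `stabilized = TRUE` (default) the numerators are the marginal childhood
#' exposure probability and the adulthood probability given childhood
#' exposure, so the total IPTW has mean near one.
#'
#' @inheritParams fit_exposure_models
#' @param stabilized Use stabilization numerators (default `TRUE`).
#' @param models Optional prefitted [fit_exposure_models()] object (must come
#'   from the same cohort).
#' @param prob_floor Predicted denominator probabilities at or below this
#'   floor raise a positivity error naming the offending subjects (default
#'   `1e-6`).
#' @return A tibble of class `lc_weights` with columns `iptw_child`,
#'   `iptw_adult`, `iptw_total`, `sampling_weight`, `final_weight`, and
#'   attributes `stabilized`, `covariate_set`, `exposure`.
#' @export
compute_iptw <- function(cohort,
                         exposure = c("cumulative", "substance",
                                      "deprivation", "abuse"),
                         covariate_set = c("base", "base+cells",
                                           "base+smoking"),
                         stabilized = TRUE,
                         models = NULL,
                         prob_floor = 1e-6) {
  exposure <- match.arg(exposure)
  covariate_set <- match.arg(covariate_set)
  cohort <- validate_cohort(cohort)
  if (is.null(models)) {
    models <- fit_exposure_models(cohort, exposure, covariate_set)
  } else if (!inherits(models, "lc_exposure_models")) {
    abort("`models` must come from fit_exposure_models().")
  }
  cols <- models$cols
  a1 <- cohort[[cols[["child"]]]]
  a2 <- cohort[[cols[["adult"]]]]

  p1 <- observed_prob(models$child_denom, cohort, a1)
  p2 <- observed_prob(models$adult_denom, cohort, a2)
  for (p in list(child = p1, adult = p2)) {
    bad <- which(p <= prob_floor)
    if (length(bad)) {
      abort(sprintf(
        "Positivity violation: predicted exposure probability <= %g for subject(s) %s.",
        prob_floor, paste(head(bad, 10), collapse = ", ")))
    }
  }
  if (stabilized) {
    s1 <- observed_prob(models$child_num, cohort, a1)
    s2 <- observed_prob(models$adult_num, cohort, a2)
  } else {
    s1 <- s2 <- rep(1, nrow(cohort))
  }

  iptw_child <- s1 / p1
  iptw_adult <- s2 / p2
  iptw_total <- iptw_child * iptw_adult
  out <- tibble::tibble(
    iptw_child = iptw_child,
    iptw_adult = iptw_adult,
    iptw_total = iptw_total,
    sampling_weight = cohort$sampling_weight,
    final_weight = combine_weights(iptw_total, cohort$sampling_weight)
  )
  structure(out, class = c("lc_weights", class(out)),
            stabilized = stabilized, covariate_set = covariate_set,
            exposure = exposure)
}

#' Compose IPTW with sampling weights
#'
#' The final analysis weight is the elementwise product of the total IPTW and
#' the survey sampling weight.
#'
#' @param iptw_total,sampling_weight Positive numeric vectors of equal length.
#' @return Numeric vector of final weights.
#' @examples
#' combine_weights(2, 1.5)
#' @export
combine_weights <- function(iptw_total, sampling_weight) {
  if (any(!is.finite(iptw_total)) || any(iptw_total <= 0)) {
    abort("`iptw_total` must be finite and positive.")
  }
  if (any(!is.finite(sampling_weight)) || any(sampling_weight <= 0)) {
    abort("`sampling_weight` must be finite and positive.")
  }
  iptw_total * sampling_weight
}

kish_neff <- function(w) sum(w)^2 / sum(w^2)

#' Summaries of a weight set
#'
#' One row per weight column with mean, min, max, 99th percentile, and the
#' Kish effective sample size `(sum w)^2 / sum(w^2)`.
#'
#' @param weights An `lc_weights` tibble from [compute_iptw()], or a numeric
#'   vector of weights.
#' @return A tibble of diagnostics.
#' @export
weight_diagnostics <- function(weights) {
  if (is.numeric(weights)) {
    weights <- tibble::tibble(weight = weights)
  }
  cols <- names(weights)[vapply(weights, is.numeric, logical(1))]
  purrr::map_dfr(cols, function(col) {
    w <- weights[[col]]
    tibble::tibble(column = col, mean = mean(w), min = min(w), max = max(w),
                   p99 = unname(quantile(w, 0.99)), n_eff = kish_neff(w))
  })
}

#' Truncate extreme weights at configurable percentiles
#'
#' Clips a weight vector (or the `iptw_total` column of an `lc_weights`
#' tibble, recomputing `final_weight`) at the given lower/upper quantiles.
#' Truncation is opt-in; no weight is truncated unless this is called.
#'
#' @param weights Numeric vector or `lc_weights` tibble.
#' @param lower,upper Quantile bounds (defaults 0.01 and 0.99).
#' @return Object of the same shape with clipped weights.
#' @export
truncate_weights <- function(weights, lower = 0.01, upper = 0.99) {
  clip <- function(w) {
    q <- quantile(w, c(lower, upper), names = FALSE)
    pmin(pmax(w, q[1]), q[2])
  }
  if (is.numeric(weights)) return(clip(weights))
  if (!inherits(weights, "lc_weights")) {
    abort("`weights` must be numeric or an lc_weights tibble.")
  }
  weights$iptw_total <- clip(weights$iptw_total)
  weights$final_weight <- combine_weights(weights$iptw_total,
                                          weights$sampling_weight)
  weights
}
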