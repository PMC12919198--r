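# Weighting-based causal mediation of childhood adversity on the outcome
# through adulthood adversity. Because the intermediate confounders
# (education, income) are affected by childhood adversity, natural direct and
# indirect effects are not identified; the package estimates their randomized
# interventional analogues (rNDE, rNIE), in which the mediator is drawn from
# its interventional distribution P(M = m | A = a). Confounding is handled
# entirely by weighting, not regression adjustment, but the two models need
# different weights:
#   - mediator model: childhood IPTW x sampling weight, so the weighted
#     P(M | A = a) standardizes over the confounder distribution and equals
#     the interventional mediator distribution. The adulthood IPTW must NOT
#     enter here: its stabilization numerator P(A2 | A1) would re-inject the
#     observed (confounded) childhood-adulthood dependence, and an
#     unstabilized or marginally-stabilized version would flatten the causal
#     dependence instead.
#   - outcome model: the full final weight (both periods' IPTW x sampling
#     weight), the joint-treatment MSM weight for E[Y | A, M].

#' Fit the weighted mediator model
#'
#' Weighted multinomial (or binomial, for a two-level mediator) logistic
#' model of the adulthood mediator given the childhood exposure, providing
#' the interventional mediator distribution `P(M = m | A = a)`.
#'
#' @param cohort Cohort tibble.
#' @param weights Positive analysis weights (final weights).
#' @param exposure_col,mediator_col Column names of the childhood exposure
#'   and adulthood mediator.
#' @return Object of class `lc_mediator_model`.
#' @export
fit_mediator_model <- function(cohort, weights,
                               exposure_col = "child_score",
                               mediator_col = "adult_score") {
  dat <- data.frame(.m = factor(cohort[[mediator_col]]),
                    .a = cohort[[exposure_col]], .w = weights)
  fit <- tryCatch(
    eval(bquote(nnet::multinom(.m ~ .a, data = dat, weights = .w,
                               trace = FALSE, maxit = 500))),
    error = function(e) abort(paste0("Mediator model failed to fit: ",
                                     conditionMessage(e))))
  if (!isTRUE(fit$convergence == 0)) {
    abort("Mediator model did not converge.")
  }
  structure(list(fit = fit,
                 levels = as.numeric(levels(dat$.m)),
                 exposure_col = exposure_col,
                 mediator_col = mediator_col),
            class = "lc_mediator_model")
}

#' Fit the weighted outcome model for mediation
#'
#' Weighted linear model `E[Y | A, M] = theta0 + theta1 A + theta2 M`
#' (`+ theta3 A M` when `interaction = TRUE`, the default, allowing the
#' effect of childhood adversity to differ by adulthood adversity).
#'
#' @inheritParams fit_mediator_model
#' @param outcome_col Outcome column name.
#' @param interaction Include the exposure-mediator interaction.
#' @return Object of class `lc_outcome_model`.
#' @export
fit_outcome_model <- function(cohort, weights,
                              exposure_col = "child_score",
                              mediator_col = "adult_score",
                              outcome_col = "outcome",
                              interaction = TRUE) {
  dat <- data.frame(.y = cohort[[outcome_col]],
                    .a = cohort[[exposure_col]],
                    .m = as.numeric(cohort[[mediator_col]]), .w = weights)
  f <- if (interaction) .y ~ .a * .m else .y ~ .a + .m
  fit <- lm(f, data = dat, weights = .w)
  if (anyNA(coef(fit))) {
    abort("Outcome model design is rank deficient.")
  }
  structure(list(fit = fit, interaction = interaction,
                 exposure_col = exposure_col, mediator_col = mediator_col,
                 outcome_col = outcome_col),
            class = "lc_outcome_model")
}

#' Interventional direct and indirect effects from fitted models
#'
#' Closed-form summation over the mediator levels:
#' `rNDE = sum_m (E(Y|a,m) - E(Y|a*,m)) P(M=m|a*)`,
#' `rNIE = sum_m E(Y|a,m) (P(M=m|a) - P(M=m|a*))`, and
#' `TE = rNDE + rNIE` (exact by construction).
#'
#' @param mediator_model From [fit_mediator_model()].
#' @param outcome_model From [fit_outcome_model()].
#' @param a,a_star Exposure contrast; defaults 1 vs 0 (a one-unit increase in
#'   the childhood cumulative score).
#' @return Named numeric vector `c(TE, rNDE, rNIE)` in outcome units.
#' @export
estimate_effects <- function(mediator_model, outcome_model, a = 1,
                             a_star = 0) {
  if (!inherits(mediator_model, "lc_mediator_model") ||
      !inherits(outcome_model, "lc_outcome_model")) {
    abort("Models must come from fit_mediator_model()/fit_outcome_model().")
  }
  if (isTRUE(a == a_star)) abort("`a` and `a_star` must differ.")
  m_levels <- mediator_model$levels

  p_at <- function(aval) {
    pr <- predict(mediator_model$fit, newdata = data.frame(.a = aval),
                  type = "probs")
    if (length(mediator_model$levels) == 2L && length(pr) == 1L) {
      pr <- c(1 - pr, pr)
    }
    as.numeric(pr)
  }
  ey <- function(aval) {
    predict(outcome_model$fit,
            newdata = data.frame(.a = aval, .m = m_levels))
  }

  p_a <- p_at(a)
  p_astar <- p_at(a_star)
  ey_a <- ey(a)
  ey_astar <- ey(a_star)

  rnde <- sum((ey_a - ey_astar) * p_astar)
  rnie <- sum(ey_a * (p_a - p_astar))
  c(TE = rnde + rnie, rNDE = rnde, rNIE = rnie)
}

mediation_cols <- function(exposure, mediator) {
  e <- if (exposure == "cumulative") "child_score" else paste0("child_", exposure)
  m <- if (mediator == "cumulative") "adult_score" else paste0("adult_", mediator)
  c(exposure = e, mediator = m)
}

#' Causal mediation of childhood adversity through adulthood adversity
#'
#' Full mediation stage: computes the final analysis weights, fits the
#' weighted mediator and outcome models (exposure-mediator interaction on by
#' default), evaluates TE, rNDE, and rNIE for the requested contrast, and
#' attaches nonparametric bootstrap percentile confidence intervals. The
#' mediator model is weighted by the childhood IPTW times the sampling
#' weight (giving the interventional mediator distribution) and the outcome
#' model by the full final weight. All weights are recomputed inside every
#' bootstrap resample so their estimation uncertainty is reflected in the
#' intervals. Resamples with a degenerate exposure or mediator are skipped
#' and counted; a warning is issued when more than 5% are skipped.
#'
#' @param cohort Cohort tibble.
#' @param exposure,mediator `"cumulative"` or an adversity type; the exposure
#'   is the childhood measure and the mediator its adulthood counterpart.
#' @param outcome Outcome column name.
#' @param covariate_set,stabilized Passed to [compute_iptw()].
#' @param interaction Include the exposure-mediator interaction (default
#'   `TRUE`).
#' @param a,a_star Exposure contrast (default 1 vs 0).
#' @param n_boot Bootstrap replicates (default 500; 0 skips the CIs).
#' @param seed Optional integer seed.
#' @return Object of class `lc_mediation`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(scenario_config("pathway", 1000), seed = 1)
#' med <- mediate_lifecourse(cohort, n_boot = 50, seed = 2)
#' tidy(med)
#' }
#' @export
mediate_lifecourse <- function(cohort,
                               exposure = c("cumulative", "substance",
                                            "deprivation", "abuse"),
                               mediator = exposure,
                               outcome = "outcome",
                               covariate_set = "base",
                               stabilized = TRUE,
                               interaction = TRUE,
                               a = 1, a_star = 0,
                               n_boot = 500,
                               seed = NULL) {
  exposure <- match.arg(exposure)
  mediator <- match.arg(mediator, c("cumulative", "substance", "deprivation",
                                    "abuse"))
  cohort <- validate_cohort(cohort)
  cols <- mediation_cols(exposure, mediator)
  set_seed_if(seed)

  point_fit <- function(dat) {
    ws <- compute_iptw(dat, exposure = exposure,
                       covariate_set = covariate_set,
                       stabilized = stabilized)
    w_mediator <- ws$iptw_child * ws$sampling_weight
    mm <- fit_mediator_model(dat, w_mediator, cols[["exposure"]],
                             cols[["mediator"]])
    om <- fit_outcome_model(dat, ws$final_weight, cols[["exposure"]],
                            cols[["mediator"]], outcome, interaction)
    estimate_effects(mm, om, a = a, a_star = a_star)
  }

  est <- point_fit(cohort)

  boot <- NULL
  n_skipped <- 0L
  if (n_boot > 0) {
    n <- nrow(cohort)
    boot <- matrix(NA_real_, n_boot, 3,
                   dimnames = list(NULL, c("TE", "rNDE", "rNIE")))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      dat <- cohort[idx, , drop = FALSE]
      if (length(unique(dat[[cols[["exposure"]]]])) < 2L ||
          length(unique(dat[[cols[["mediator"]]]])) < 2L) {
        n_skipped <- n_skipped + 1L
        next
      }
      res <- tryCatch(point_fit(dat), error = function(e) NULL)
      if (is.null(res)) {
        n_skipped <- n_skipped + 1L
      } else {
        boot[b, ] <- res
      }
    }
    if (n_skipped > 0.05 * n_boot) {
      warn(sprintf("%d of %d bootstrap resamples were skipped (degenerate exposure/mediator or failed fit).",
                   n_skipped, n_boot))
    }
    boot <- boot[stats::complete.cases(boot), , drop = FALSE]
    if (nrow(boot) < 2) abort("Too few successful bootstrap resamples.")
  }

  ci <- if (!is.null(boot)) {
    purrr::map_dfr(c("TE", "rNDE", "rNIE"), function(term) {
      q <- quantile(boot[, term], c(0.025, 0.975), names = FALSE)
      tibble::tibble(term = term, conf.low = q[1], conf.high = q[2])
    })
  } else {
    tibble::tibble(term = c("TE", "rNDE", "rNIE"),
                   conf.low = NA_real_, conf.high = NA_real_)
  }

  structure(list(
    estimates = est,
    ci = ci,
    contrast = c(a = a, a_star = a_star),
    interaction = interaction,
    n_boot = if (is.null(boot)) 0L else nrow(boot),
    n_skipped = n_skipped,
    exposure = exposure, mediator = mediator, outcome = outcome,
    boot = boot
  ), class = "lc_mediation")
}

#' @method tidy lc_mediation
#' @export
tidy.lc_mediation <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(term = names(x$estimates),
                   estimate = unname(x$estimates)),
    x$ci, by = "term")
}

#' Does the indirect-effect interval exclude zero?
#'
#' The operational test for the pathway hypothesis: `TRUE` when the 95%
#' bootstrap CI for rNIE excludes zero.
#'
#' @param mediation An `lc_mediation` object.
#' @return Logical (or `NA` when no bootstrap CI is available).
#' @export
rnie_excludes_zero <- function(mediation) {
  ci <- mediation$ci[mediation$ci$term == "rNIE", ]
  if (is.na(ci$conf.low)) return(NA)
  ci$conf.low > 0 || ci$conf.high < 0
}

#' @export
print.lc_mediation <- function(x, ...) {
  cat(sprintf("Interventional mediation: %s (child) -> %s (adult) -> %s\n",
              x$exposure, x$mediator, x$outcome))
  cat(sprintf("  contrast a = %s vs a* = %s; interaction %s; %d bootstrap resamples\n",
              x$contrast[["a"]], x$contrast[["a_star"]],
              if (x$interaction) "on" else "off", x$n_boot))
  print(tidy(x), ...)
  invisible(x)
}

#' @method autoplot lc_mediation
#' @export
autoplot.lc_mediation <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = c("TE", "rNDE", "rNIE"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "effect (outcome units)",
                  title = "Total, direct, and indirect effects")
}
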