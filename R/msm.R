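# Conventional marginal structural model, used as the cross-check of the
# Bayesian life-course fit: weighted least squares of the outcome on the two
# period scores with the final analysis weights. The sum of the two
# coefficients is the additive life-course effect; their ratio to that sum
# gives implied period weights comparable to the Bayesian posterior means.

#' Fit the marginal structural model sensitivity analysis
#'
#' Weighted linear regression `outcome ~ child + adult` with the final
#' analysis weights. Reports period coefficients, their additive life-course
#' effect, implied period weights (flagged undefined when the coefficients
#' disagree in sign), robust (HC0 sandwich) standard errors, and optional
#' subject-level bootstrap percentile CIs with weight recomputation.
#'
#' @param cohort Cohort tibble.
#' @param weights Optional precomputed final weights; computed via
#'   [compute_iptw()] when `NULL`.
#' @param exposure,covariate_set,stabilized Passed to [compute_iptw()].
#' @param outcome,child,adult Column names.
#' @param n_boot Bootstrap replicates for percentile CIs (default 0: robust
#'   CIs only).
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class `lc_msm`.
#' @export
fit_msm <- function(cohort, weights = NULL, exposure = "cumulative",
                    covariate_set = "base", stabilized = TRUE,
                    outcome = "outcome", child = "child_score",
                    adult = "adult_score", n_boot = 0, seed = NULL) {
  cohort <- validate_cohort(cohort)
  set_seed_if(seed)
  w <- weights %||% compute_iptw(cohort, exposure = exposure,
                                 covariate_set = covariate_set,
                                 stabilized = stabilized)$final_weight

  wls <- function(dat, wt) {
    d <- data.frame(.y = dat[[outcome]], .c = dat[[child]],
                    .a = dat[[adult]], .w = wt)
    fit <- lm(.y ~ .c + .a, data = d, weights = .w)
    if (anyNA(coef(fit))) abort("MSM design matrix is singular.")
    fit
  }

  fit <- wls(cohort, w)
  beta <- coef(fit)
  beta_child <- unname(beta[".c"])
  beta_adult <- unname(beta[".a"])
  effect <- beta_child + beta_adult
  same_sign <- sign(beta_child) == sign(beta_adult) && effect != 0
  implied <- if (same_sign) {
    c(child = beta_child / effect, adult = beta_adult / effect)
  } else {
    c(child = NA_real_, adult = NA_real_)
  }

  vc <- sandwich::vcovHC(fit, type = "HC0")
  se <- sqrt(diag(vc))[c(".c", ".a")]
  se_effect <- sqrt(vc[".c", ".c"] + vc[".a", ".a"] + 2 * vc[".c", ".a"])

  boot <- NULL
  if (n_boot > 0) {
    n <- nrow(cohort)
    boot <- matrix(NA_real_, n_boot, 3,
                   dimnames = list(NULL, c("beta_child", "beta_adult",
                                           "lifecourse_effect")))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      dat <- cohort[idx, , drop = FALSE]
      res <- tryCatch({
        wb <- compute_iptw(dat, exposure = exposure,
                           covariate_set = covariate_set,
                           stabilized = stabilized)$final_weight
        cb <- coef(wls(dat, wb))
        c(cb[".c"], cb[".a"], cb[".c"] + cb[".a"])
      }, error = function(e) rep(NA_real_, 3))
      boot[b, ] <- res
    }
    boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  }

  ci_from <- function(term, est, se_est) {
    if (!is.null(boot) && nrow(boot) >= 2) {
      q <- quantile(boot[, term], c(0.025, 0.975), names = FALSE)
      c(q[1], q[2])
    } else {
      est + c(-1, 1) * 1.96 * se_est
    }
  }

  summary_tbl <- tibble::tibble(
    term = c("beta_child", "beta_adult", "lifecourse_effect"),
    estimate = c(beta_child, beta_adult, effect),
    std.error = c(unname(se), se_effect)
  )
  summary_tbl$conf.low <- NA_real_
  summary_tbl$conf.high <- NA_real_
  for (i in seq_len(nrow(summary_tbl))) {
    ci <- ci_from(summary_tbl$term[i], summary_tbl$estimate[i],
                  summary_tbl$std.error[i])
    summary_tbl$conf.low[i] <- ci[1]
    summary_tbl$conf.high[i] <- ci[2]
  }

  structure(list(
    summary = summary_tbl,
    implied_weights = implied,
    weights_defined = same_sign,
    n_boot = if (is.null(boot)) 0L else nrow(boot),
    fit = fit
  ), class = "lc_msm")
}

#' @method tidy lc_msm
#' @export
tidy.lc_msm <- function(x, ...) x$summary

#' @method glance lc_msm
#' @export
glance.lc_msm <- function(x, ...) {
  tibble::tibble(
    lifecourse_effect = x$summary$estimate[x$summary$term == "lifecourse_effect"],
    implied_w_child = x$implied_weights[["child"]],
    implied_w_adult = x$implied_weights[["adult"]],
    weights_defined = x$weights_defined,
    n_boot = x$n_boot
  )
}

#' @export
print.lc_msm <- function(x, ...) {
  cat("Marginal structural model (weighted least squares)\n")
  print(x$summary, ...)
  if (x$weights_defined) {
    cat(sprintf("  implied weights: child %.2f, adult %.2f\n",
                x$implied_weights[["child"]], x$implied_weights[["adult"]]))
  } else {
    cat("  implied weights undefined (period coefficients differ in sign)\n")
  }
  invisible(x)
}
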