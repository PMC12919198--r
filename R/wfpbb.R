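# Weighted finite population Bayesian bootstrap (Polya posterior).
#
# The weighted sample is expanded into a synthetic target population by a
# weighted Polya urn: with weights rescaled to sum to the population size N,
# each subject starts the urn with mass (w_i - 1) and every drawn synthetic
# unit adds mass (N - n)/n to its subject. The N - n sequential urn draws are
# generated in one shot through the urn's Dirichlet-multinomial
# representation: p ~ Dirichlet((w_i - 1) * n / (N - n)), counts ~
# Multinomial(N - n, p). Each replicate is then an equal-size unit-weight
# sample from the expanded population.

#' Expand a weighted sample into a synthetic population (Polya posterior)
#'
#' Rescales `weights` to sum to `pop_size` and draws how many units of the
#' synthetic population each subject represents. Marginally, subject `i`'s
#' expected count equals its rescaled weight. Subjects whose rescaled weight
#' falls below one contribute only themselves (their urn mass is floored at
#' zero).
#'
#' @param weights Positive weights, one per subject.
#' @param pop_size Target population size `N >= length(weights)`.
#' @param seed Optional integer seed.
#' @return Integer counts per subject summing exactly to `pop_size`.
#' @export
polya_expand <- function(weights, pop_size, seed = NULL) {
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort("`weights` must be finite and positive.")
  }
  n <- length(weights)
  pop_size <- as.integer(round(pop_size))
  if (pop_size < n) {
    abort("`pop_size` must be at least the sample size.")
  }
  set_seed_if(seed)
  if (pop_size == n) return(rep(1L, n))

  w <- weights * pop_size / sum(weights)
  n_extra <- pop_size - n
  alpha <- pmax(w - 1, 0) * n / n_extra
  if (all(alpha == 0)) {
    # all mass floored (near-uniform weights): spread the extra units uniformly
    alpha <- rep(1, n)
  }
  g <- rgamma(n, shape = alpha)
  if (sum(g) == 0) g[sample.int(n, 1)] <- 1
  extra <- as.integer(rmultinom(1, n_extra, g / sum(g)))
  counts <- 1L + extra
  stopifnot(sum(counts) == pop_size)
  counts
}

#' Draw one unit-weight replicate from an expanded population
#'
#' Simple random sample of `n` units from the synthetic population described
#' by `counts`; every sampled unit carries weight one.
#'
#' @param counts Integer counts from [polya_expand()].
#' @param n Replicate size (the analytic sample size).
#' @param seed Optional integer seed.
#' @param replace Sample with replacement instead (default `FALSE`, matching
#'   an equal-size random sample from the reformed population).
#' @return Integer vector of `n` subject row indices (with multiplicity).
#' @export
draw_replicate <- function(counts, n, seed = NULL, replace = FALSE) {
  pop_size <- sum(counts)
  if (!replace && n > pop_size) {
    abort("`n` cannot exceed the population size when sampling without replacement.")
  }
  set_seed_if(seed)
  population <- rep.int(seq_along(counts), counts)
  idx <- population[sample.int(length(population), n, replace = replace)]
  as.integer(idx)
}

#' Generate weighted finite population Bayesian bootstrap replicates
#'
#' For each replicate, expands the weighted cohort into a synthetic target
#' population via [polya_expand()] and redraws an equal-size unit-weight
#' sample via [draw_replicate()]. Averaged over replicates, the replicate
#' mean of any column is an unbiased estimate of its Hajek (weighted) mean,
#' so downstream models can be fitted unweighted on each replicate.
#'
#' @param cohort Cohort tibble (only its row count is used here).
#' @param final_weights Positive per-subject analysis weights (IPTW times
#'   sampling weight).
#' @param n_replicates Number of replicates (default 200).
#' @param pop_size Synthetic population size. Default
#'   `max(round(sum(final_weights)), 20 * n)`: the weight total when weights
#'   are on a population (gross-up) scale, and a 20-fold expansion when they
#'   are normalized to unit mean, in which case the weight total equals the
#'   sample size and would leave no population to impute.
#' @param seed Optional integer seed; identical seeds give identical
#'   replicate index lists.
#' @param replace Passed to [draw_replicate()].
#' @return A tibble with columns `replicate_id` and `row` (subject row index,
#'   with multiplicity), `n_replicates * nrow(cohort)` rows.
#' @export
generate_replicates <- function(cohort, final_weights, n_replicates = 200,
                                pop_size = NULL, seed = NULL,
                                replace = FALSE) {
  n <- nrow(cohort)
  if (length(final_weights) != n) {
    abort("`final_weights` must have one weight per cohort row.")
  }
  if (any(!is.finite(final_weights)) || any(final_weights <= 0)) {
    abort("`final_weights` must be finite and positive.")
  }
  if (n_replicates < 1) abort("`n_replicates` must be positive.")
  pop_size <- pop_size %||% max(round(sum(final_weights)), 20L * n)
  set_seed_if(seed)
  rows <- purrr::map(seq_len(n_replicates), function(b) {
    counts <- polya_expand(final_weights, pop_size)
    draw_replicate(counts, n, replace = replace)
  })
  tibble::tibble(
    replicate_id = rep(seq_len(n_replicates), each = n),
    row = unlist(rows)
  )
}
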