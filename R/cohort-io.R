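# Cohort schema, validation, and CSV round-trip. One schema serves both
# synthetic cohorts and any real cohort prepared to the same layout.

COHORT_REQUIRED <- c(
  "sex", "age", "parental_education", "nativity",
  "child_substance", "child_deprivation", "child_abuse", "child_score",
  "own_education", "household_income",
  "adult_substance", "adult_deprivation", "adult_abuse", "adult_score",
  "outcome", "sampling_weight"
)
COHORT_BINARY <- c(
  "sex", "parental_education", "nativity",
  "child_substance", "child_deprivation", "child_abuse",
  "own_education", "household_income",
  "adult_substance", "adult_deprivation", "adult_abuse"
)
CELL_COLS <- c("cell_neu", "cell_cd4t", "cell_cd8t", "cell_bcell",
               "cell_nk", "cell_mono")

#' Validate a cohort table
#'
#' Checks the per-subject cohort schema: all required columns present, no
#' missing values (imputation is out of scope, so missingness is rejected
#' rather than handled), adversity indicators strictly 0/1, cumulative scores
#' equal to the sum of their three indicators, positive sampling weights, and
#' cell-type proportions (when present) summing to one. Violations raise an
#' error naming the offending column and rows.
#'
#' @param cohort A data frame.
#' @return The cohort, invisibly, as a tibble.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame.")
  cohort <- tibble::as_tibble(cohort)

  missing_cols <- setdiff(COHORT_REQUIRED, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  for (col in COHORT_REQUIRED) {
    if (anyNA(cohort[[col]])) {
      rows <- which(is.na(cohort[[col]]))
      abort(sprintf("Column `%s` has missing values (rows %s); impute or drop before analysis.",
                    col, paste(head(rows, 5), collapse = ", ")))
    }
  }
  for (col in COHORT_BINARY) {
    bad <- which(!cohort[[col]] %in% c(0, 1))
    if (length(bad)) {
      abort(sprintf("Column `%s` must be 0/1; offending row(s): %s.",
                    col, paste(head(bad, 5), collapse = ", ")))
    }
  }
  for (period in c("child", "adult")) {
    score <- cohort[[paste0(period, "_score")]]
    expected <- cumulative_score(cohort[[paste0(period, "_substance")]],
                                 cohort[[paste0(period, "_deprivation")]],
                                 cohort[[paste0(period, "_abuse")]])
    bad <- which(score != expected)
    if (length(bad)) {
      abort(sprintf("`%s_score` must equal the sum of its three indicators; offending row(s): %s.",
                    period, paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (any(cohort$sampling_weight <= 0)) {
    bad <- which(cohort$sampling_weight <= 0)
    abort(sprintf("`sampling_weight` must be positive; offending row(s): %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (all(CELL_COLS %in% names(cohort))) {
    tot <- rowSums(cohort[CELL_COLS])
    bad <- which(abs(tot - 1) > 1e-6)
    if (length(bad)) {
      abort(sprintf("Cell-type proportions must sum to 1; offending row(s): %s.",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' @param cohort A validated cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Read and validate a cohort table from CSV
#'
#' @param path CSV path with the documented cohort header.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE,
                            progress = FALSE)
  if ("smoking" %in% names(cohort)) {
    cohort$smoking <- factor(cohort$smoking,
                             levels = c("never", "former", "current"))
  }
  for (col in c(COHORT_BINARY, "child_score", "adult_score")) {
    if (col %in% names(cohort)) cohort[[col]] <- as.integer(cohort[[col]])
  }
  validate_cohort(cohort)
  tibble::as_tibble(cohort)
}

#' Write the generating truth of a synthetic cohort to JSON
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  truth <- cohort_truth(cohort)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
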