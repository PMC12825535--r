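#' Derive a reproducible child seed from a parent seed
#'
#' Stage seeds are derived deterministically from a single global seed so
#' that changing one stage's options never perturbs another stage's random
#' stream. The derivation is a small integer hash kept below 2^31.
#'
#' @param seed Parent integer seed.
#' @param tag Character label of the consuming stage.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 2654435761 + h * 97 + 1) %% .Machine$integer.max)
}

# Internal: set RNG state if a seed is supplied.
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Internal: assert columns exist in a data frame.
check_columns <- function(df, cols, where = "cohort") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("missing %s column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Baseline covariates used throughout the analyses
#'
#' The nine baseline covariates every adjusted model conditions on:
#' age, sex, ethnicity, deprivation index, smoking, alcohol, BMI,
#' hypertension and diabetes.
#'
#' @return Character vector of column names.
#' @export
baseline_covariates <- function() {
  c("age", "sex", "ethnicity", "deprivation_index", "smoking",
    "alcohol", "bmi", "hypertension", "diabetes")
}
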