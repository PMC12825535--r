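#' Apply the cohort exclusion cascade
#'
#' Removes, in order, (1) participants with a prior cancer history and
#' (2) participants with any missing baseline covariate. The order matters:
#' a participant failing both criteria is counted only at the first step.
#'
#' @param cohort Cohort data.frame with a `prior_cancer` flag.
#' @param covariates Covariate columns whose completeness is required;
#'   defaults to the nine baseline covariates.
#' @return A list with `cohort` (filtered data.frame) and `log`
#'   (named integer vector of per-step removal counts).
#' @export
apply_exclusions <- function(cohort, covariates = baseline_covariates()) {
  check_columns(cohort, c("prior_cancer", covariates))
  n0 <- nrow(cohort)
  keep1 <- cohort$prior_cancer != 1 | is.na(cohort$prior_cancer)
  step1 <- cohort[keep1, , drop = FALSE]
  n_prior <- n0 - nrow(step1)
  complete <- stats::complete.cases(step1[, covariates, drop = FALSE])
  out <- step1[complete, , drop = FALSE]
  n_missing <- nrow(step1) - nrow(out)
  if (nrow(out) == 0L) stop("exclusion cascade removed every participant",
                            call. = FALSE)
  list(cohort = out,
       log = c(prior_cancer = n_prior, missing_covariates = n_missing))
}

#' Drop proteins with excessive missingness
#'
#' Removes proteins whose missing fraction strictly exceeds `max_missing`
#' (a protein missing in exactly 20% of rows is retained at the default).
#' Column order of the retained proteins is preserved.
#'
#' @param matrix Participants x proteins numeric matrix with `NA` missing.
#' @param max_missing Maximum tolerated missing fraction; default 0.20.
#' @return The filtered matrix, with attribute `dropped` listing removed
#'   protein names.
#' @export
filter_proteins <- function(matrix, max_missing = 0.20) {
  frac <- colMeans(is.na(matrix))
  drop <- frac > max_missing
  out <- matrix[, !drop, drop = FALSE]
  attr(out, "dropped") <- colnames(matrix)[drop]
  out
}

#' k-nearest-neighbour imputation of a protein matrix
#'
#' Imputes each missing cell (i, p) with the average, over the k proteins
#' nearest to protein p, of those proteins' observed values in row i.
#' Proximity between two proteins is the Euclidean distance computed over
#' rows where both are observed, normalised by the number of such rows so
#' that pairs with different overlap are comparable. A protein with no
#' complete peer, or a row where no neighbour is observed, falls back to
#' the protein mean, with a warning.
#'
#' @param matrix Participants x proteins numeric matrix with `NA` missing.
#' @param k Number of neighbouring proteins to average; default 10.
#' @return The completed matrix; observed cells are untouched.
#' @export
knn_impute <- function(matrix, k = 10) {
  p <- ncol(matrix)
  if (!anyNA(matrix)) return(matrix)
  if (p == 1L) {
    matrix[is.na(matrix)] <- mean(matrix, na.rm = TRUE)
    warning("single-protein matrix: imputed with the protein mean")
    return(matrix)
  }
  obs <- !is.na(matrix)
  col_mean <- colMeans(matrix, na.rm = TRUE)
  # pairwise normalised Euclidean distances between protein columns
  d <- matrix(Inf, p, p)
  for (a in seq_len(p - 1)) {
    xa <- matrix[, a]
    for (b in (a + 1):p) {
      both <- obs[, a] & obs[, b]
      if (any(both)) {
        d[a, b] <- d[b, a] <- sqrt(mean((xa[both] - matrix[both, b])^2))
      }
    }
  }
  out <- matrix
  used_fallback <- FALSE
  for (pcol in which(colSums(!obs) > 0L)) {
    ord <- order(d[pcol, ])                       # Inf (no overlap) sorts last
    nbrs <- ord[is.finite(d[pcol, ord])]
    nbrs <- utils::head(nbrs, k)
    rows <- which(!obs[, pcol])
    for (i in rows) {
      vals <- matrix[i, nbrs]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        out[i, pcol] <- mean(vals)
      } else {
        out[i, pcol] <- col_mean[pcol]
        used_fallback <- TRUE
      }
    }
    if (!length(nbrs)) used_fallback <- TRUE
  }
  if (used_fallback) {
    warning("some cells had no observed neighbour; protein mean used")
  }
  out
}

#' Random derivation/replication split
#'
#' Simple random split without stratification; the derivation set receives
#' `floor(frac * N)` participants.
#'
#' @param cohort Cohort data.frame with `participant_id`.
#' @param frac Derivation fraction in (0, 1); default 0.80.
#' @param seed Integer seed making the split reproducible.
#' @return A list with character id vectors `derivation` and `replication`.
#' @export
split_cohort <- function(cohort, frac = 0.80, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  ids <- cohort$participant_id
  set_seed_if(seed)
  n_deriv <- floor(frac * length(ids))
  deriv <- sample(ids, n_deriv)
  list(derivation = sort(deriv),
       replication = sort(setdiff(ids, deriv)))
}
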