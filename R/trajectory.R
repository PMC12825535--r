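#' Default lead-time grid for trajectory curves
#'
#' Descending grid from 15 to 0 years before diagnosis in 0.25-year steps.
#'
#' @return Numeric vector of lead times.
#' @export
lead_time_grid <- function() seq(15, 0, by = -0.25)

#' Match event-free controls to cases by sex and baseline age
#'
#' Each case receives `ratio` controls with the same sex and the nearest
#' baseline age, drawn without replacement across cases. Cases are
#' processed in a seeded random order and age ties are broken by the same
#' seeded stream, so the assignment is deterministic given the seed. If
#' the same-sex pool is exhausted a case receives fewer controls and the
#' shortfall is recorded.
#'
#' @param cohort Cohort data.frame with `participant_id`, `event`, `age`,
#'   `sex`.
#' @param ratio Controls per case; default 10.
#' @param seed Integer seed.
#' @return A list of class `matched_sets`; each element has `case_id`,
#'   `control_ids`, and `short` (number of controls short of `ratio`).
#' @export
match_controls <- function(cohort, ratio = 10, seed = 1L) {
  check_columns(cohort, c("participant_id", "event", "age", "sex"))
  set_seed_if(seed)
  cases <- cohort[cohort$event == 1, , drop = FALSE]
  controls <- cohort[cohort$event == 0, , drop = FALSE]
  if (nrow(cases) == 0L) stop("no cases to match", call. = FALSE)
  case_order <- sample(nrow(cases))
  used <- character(0)
  sets <- vector("list", nrow(cases))
  for (idx in seq_along(case_order)) {
    cs <- cases[case_order[idx], ]
    pool <- controls[controls$sex == cs$sex &
                       !(controls$participant_id %in% used), , drop = FALSE]
    ord <- order(abs(pool$age - cs$age), stats::runif(nrow(pool)))
    take <- utils::head(pool$participant_id[ord], ratio)
    used <- c(used, take)
    sets[[idx]] <- list(case_id = cs$participant_id,
                        control_ids = take,
                        short = as.integer(ratio - length(take)))
  }
  short_total <- sum(vapply(sets, `[[`, integer(1), "short"))
  if (short_total > 0) {
    warning(sprintf("control pool exhausted: %d control slots unfilled",
                    short_total))
  }
  structure(sets, class = "matched_sets")
}

#' Residualize a protein matrix on covariates fitted in controls
#'
#' For each protein, an ordinary linear regression of NPX on the
#' covariates is fitted using event-free controls only; the fitted
#' prediction is then subtracted from every participant's value. Fitting
#' on controls keeps case-specific signal out of the adjustment.
#'
#' @param matrix Complete participants x proteins matrix, rows named by
#'   participant id.
#' @param cohort Cohort data.frame aligned by `participant_id`.
#' @param covariates Covariate columns; default the nine baseline ones.
#' @return Matrix of residuals, same dimensions and dimnames.
#' @export
residualize <- function(matrix, cohort, covariates = baseline_covariates()) {
  check_columns(cohort, c("participant_id", "event", covariates))
  if (anyNA(matrix)) stop("matrix must be complete", call. = FALSE)
  matrix <- matrix[match(cohort$participant_id, rownames(matrix)), ,
                   drop = FALSE]
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = " + "))),
    data = cohort)
  ctrl <- cohort$event == 0
  qr_c <- qr(X[ctrl, , drop = FALSE])
  if (qr_c$rank < ncol(X)) {
    bad <- colnames(X)[qr_c$pivot[(qr_c$rank + 1):ncol(X)]]
    stop("singular covariate design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qr_c, matrix[ctrl, , drop = FALSE])
  matrix - X %*% coefs
}

#' Case z-scores relative to matched controls
#'
#' For each case and protein, `z = (case - mean(controls)) / sd(controls)`
#' using that case's own matched control set (SD with the n-1
#' denominator). A zero control SD yields `NA` for that case-protein.
#'
#' @param matrix Adjusted participants x proteins matrix, rows named by
#'   participant id.
#' @param matched A `matched_sets` object from [match_controls()].
#' @return Cases x proteins matrix of z-scores, rows named by case id.
#' @export
zscore_cases <- function(matrix, matched) {
  stopifnot(inherits(matched, "matched_sets"))
  res <- vapply(matched, function(ms) {
    if (length(ms$control_ids) < 2L) {
      return(rep(NA_real_, ncol(matrix)))
    }
    ctrl <- matrix[ms$control_ids, , drop = FALSE]
    mu <- colMeans(ctrl)
    sdv <- apply(ctrl, 2, stats::sd)
    out <- (matrix[ms$case_id, ] - mu) / sdv
    out[sdv == 0] <- NA_real_
    out
  }, numeric(ncol(matrix)))
  if (is.null(dim(res))) res <- rbind(res)   # single-protein matrix
  z <- t(res)
  rownames(z) <- vapply(matched, `[[`, character(1), "case_id")
  colnames(z) <- colnames(matrix)
  z
}

#' LOESS trajectory curve for one protein
#'
#' Local linear regression (tricube weights, degree 1, span 0.75 by
#' default) of case z-scores on lead time, evaluated on a common grid.
#' Predictions are restricted to the observed lead-time range; grid points
#' outside it are `NA` (no extrapolation).
#'
#' @param lead_time Case lead times in years.
#' @param z Case z-scores, same length.
#' @param span LOESS span; default 0.75.
#' @param degree Local polynomial degree; default 1 (degree 2 available
#'   for parity with other implementations).
#' @param grid Evaluation grid; default [lead_time_grid()].
#' @return Numeric vector of predictions on `grid`.
#' @export
fit_loess <- function(lead_time, z, span = 0.75, degree = 1,
                      grid = lead_time_grid()) {
  ok <- is.finite(lead_time) & is.finite(z)
  lead_time <- lead_time[ok]; z <- z[ok]
  if (length(z) < 10L) stop("need at least 10 case points", call. = FALSE)
  fit <- stats::loess(z ~ lead_time, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pred <- rep(NA_real_, length(grid))
  inside <- grid >= min(lead_time) & grid <= max(lead_time)
  pred[inside] <- stats::predict(fit, data.frame(lead_time = grid[inside]))
  pred
}

#' Abnormality crossings and sustained onset of a trajectory curve
#'
#' Records every contiguous run of grid points where the curve exceeds the
#' threshold, and the sustained onset: the earliest lead time of the final
#' exceedance run, provided that run persists to the end of the observed
#' grid (lead time closest to diagnosis). A curve that dips back below the
#' threshold before diagnosis has crossings but no sustained onset.
#'
#' @param curve Curve values on `grid` (`NA` outside the observed range).
#' @param threshold Abnormality threshold in z-units; default 0.45.
#' @param grid Lead-time grid, descending; default [lead_time_grid()].
#' @return A list with `crossings` (data.frame of `from`, `to` lead times,
#'   `from >= to`) and `onset` (years, or `NA` if never sustained).
#' @export
call_abnormal <- function(curve, threshold = 0.45, grid = lead_time_grid()) {
  stopifnot(length(curve) == length(grid))
  def <- which(!is.na(curve))
  if (!length(def)) {
    return(list(crossings = data.frame(from = numeric(0), to = numeric(0)),
                onset = NA_real_))
  }
  above <- curve > threshold
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  crossings <- data.frame(from = grid[starts[runs]], to = grid[ends[runs]])
  onset <- NA_real_
  last_def <- def[length(def)]     # grid index closest to diagnosis
  if (length(runs)) {
    fin <- runs[length(runs)]
    if (ends[fin] >= last_def) onset <- grid[starts[fin]]
  }
  list(crossings = crossings, onset = onset)
}

#' Fit trajectory curves for every protein
#'
#' Convenience wrapper applying [fit_loess()] and [call_abnormal()]
#' protein-wise to a case z-score matrix.
#'
#' @param z Cases x proteins z-score matrix.
#' @param lead_time Case lead times, aligned with rows of `z`.
#' @inheritParams fit_loess
#' @param threshold Abnormality threshold; default 0.45.
#' @return A list of class `trajectory_set` with `grid`, `curves`
#'   (grid x proteins matrix), `onset` (named vector), and `crossings`
#'   (named list of data.frames).
#' @export
fit_trajectories <- function(z, lead_time, span = 0.75, degree = 1,
                             grid = lead_time_grid(), threshold = 0.45) {
  curves <- apply(z, 2, function(col)
    fit_loess(lead_time, col, span = span, degree = degree, grid = grid))
  calls <- apply(curves, 2, call_abnormal, threshold = threshold,
                 grid = grid, simplify = FALSE)
  structure(list(
    grid = grid,
    curves = curves,
    onset = vapply(calls, `[[`, numeric(1), "onset"),
    crossings = lapply(calls, `[[`, "crossings")
  ), class = "trajectory_set")
}

#' Cluster trajectory curves
#'
#' Hierarchical clustering uses the maximum (Chebyshev) distance between
#' curves — the largest absolute difference over the grid — with complete
#' linkage, cutting the tree at `k`. The k-means sensitivity variant runs
#' Lloyd-type clustering on the raw prediction vectors with a seeded
#' multi-start. Grid points where any curve is undefined are dropped
#' before computing distances. Identical curves tie at distance zero and
#' resolve by input order.
#'
#' @param curves Grid x proteins matrix of curve predictions (or a
#'   `trajectory_set`).
#' @param k Number of clusters; default 4.
#' @param method "hierarchical" (default) or "kmeans".
#' @param seed Integer seed (used by k-means).
#' @return A list with integer `labels` (named by protein) and either
#'   `tree` (an `hclust`) or `centers` (k-means centroids).
#' @export
cluster_trajectories <- function(curves, k = 4,
                                 method = c("hierarchical", "kmeans"),
                                 seed = 1L) {
  method <- match.arg(method)
  if (inherits(curves, "trajectory_set")) curves <- curves$curves
  keep <- stats::complete.cases(curves)   # rows = grid points
  x <- t(curves[keep, , drop = FALSE])    # proteins x grid
  if (nrow(x) < k) stop("need at least k curves", call. = FALSE)
  if (method == "hierarchical") {
    d <- stats::dist(x, method = "maximum")
    tree <- stats::hclust(d, method = "complete")
    labels <- stats::cutree(tree, k = k)
    list(labels = labels, tree = tree)
  } else {
    set_seed_if(seed)
    km <- stats::kmeans(x, centers = k, nstart = 25, iter.max = 100)
    list(labels = stats::setNames(km$cluster, rownames(x)),
         centers = km$centers)
  }
}
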