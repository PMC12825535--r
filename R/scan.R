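#' Proteome-wide Cox proportional-hazards association scan
#'
#' Fits one Cox model per protein: the protein NPX value (standardized to
#' SD 1 within the analysis set) enters as a single term alongside the
#' adjustment covariates. Reports per-SD hazard ratios with Wald 95% CIs
#' and p-values, Benjamini-Hochberg q-values, a Bonferroni significance
#' flag at `alpha / M`, and a Schoenfeld-residual proportional-hazards
#' test per protein term. Ties are handled with the Efron approximation.
#'
#' @param cohort Cohort data.frame with `followup_time` and `event`.
#' @param matrix Complete participants x proteins matrix, rows aligned
#'   with (or named by) `cohort$participant_id`.
#' @param covariates Adjustment covariate columns; default the nine
#'   baseline covariates. May be empty.
#' @param alpha Family-wise significance level; default 0.05.
#' @param family_size Multiplicity family size M; defaults to the number
#'   of proteins actually tested. Override to reproduce a declared family.
#' @param ph_threshold p-value threshold for flagging a proportional-
#'   hazards violation; default 0.01.
#' @param compute_ph Compute the Schoenfeld test per protein (default
#'   TRUE); disable for large calibration sweeps.
#' @return A data.frame of class `scan_result`, one row per protein, with
#'   columns `protein`, `log_hr`, `se`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `fdr_q`, `bonferroni_sig`, `schoenfeld_p`, `ph_violation`,
#'   `n_events`. Failed fits carry `NA` statistics. The Bonferroni
#'   threshold and family size are attached as attributes.
#' @export
pwas_scan <- function(cohort, matrix, covariates = baseline_covariates(),
                      alpha = 0.05, family_size = NULL,
                      ph_threshold = 0.01, compute_ph = TRUE) {
  check_columns(cohort, c("followup_time", "event", covariates))
  if (anyNA(matrix)) stop("protein matrix must be complete (impute first)",
                          call. = FALSE)
  if (sum(cohort$event) == 0L) stop("no events in the analysis set",
                                    call. = FALSE)
  if (!is.null(rownames(matrix)) && "participant_id" %in% names(cohort)) {
    matrix <- matrix[match(cohort$participant_id, rownames(matrix)), ,
                     drop = FALSE]
  }
  stopifnot(nrow(matrix) == nrow(cohort))

  proteins <- colnames(matrix)
  n_events <- sum(cohort$event)
  base <- cohort[, c("followup_time", "event", covariates), drop = FALSE]
  rhs <- paste(c("x", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(followup_time, event) ~", rhs))

  fit_one <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(NULL)
    base$x <- (x - mean(x)) / s
    fit <- tryCatch(
      suppressWarnings(survival::coxph(fml, data = base, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)[["x"]])) return(NULL)
    beta <- stats::coef(fit)[["x"]]
    se <- sqrt(diag(fit$var))[[1]]
    zph_p <- NA_real_
    if (compute_ph) {
      zph_p <- tryCatch(survival::cox.zph(fit)$table["x", "p"],
                        error = function(e) NA_real_)
    }
    c(beta = beta, se = se, zph = zph_p)
  }

  res <- lapply(seq_along(proteins), function(j) fit_one(matrix[, j]))
  beta <- vapply(res, function(r) if (is.null(r)) NA_real_ else r[["beta"]],
                 numeric(1))
  se <- vapply(res, function(r) if (is.null(r)) NA_real_ else r[["se"]],
               numeric(1))
  zph <- vapply(res, function(r) if (is.null(r)) NA_real_ else r[["zph"]],
                numeric(1))
  p <- 2 * stats::pnorm(-abs(beta / se))

  m <- if (is.null(family_size)) sum(!is.na(p)) else family_size
  threshold <- alpha / m
  out <- data.frame(
    protein = proteins,
    log_hr = beta,
    se = se,
    hr = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    p = p,
    fdr_q = stats::p.adjust(p, method = "BH"),
    bonferroni_sig = !is.na(p) & p < threshold,
    schoenfeld_p = zph,
    ph_violation = !is.na(zph) & zph < ph_threshold,
    n_events = n_events,
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "family_size") <- m
  attr(out, "bonferroni_threshold") <- threshold
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Schoenfeld-residual proportional-hazards check for a fitted Cox model
#'
#' Correlation-based test of the proportional-hazards assumption for one
#' fitted model, flagging the first (protein) term when its p-value falls
#' below the threshold.
#'
#' @param fit A fitted `coxph` model.
#' @param threshold Violation threshold; default 0.01.
#' @param term Name of the term to test; defaults to the first coefficient.
#' @return A list with `schoenfeld_p` and logical `violation`
#'   (`NA` if the test could not be computed).
#' @export
ph_check <- function(fit, threshold = 0.01, term = NULL) {
  stopifnot(inherits(fit, "coxph"))
  if (is.null(term)) term <- names(stats::coef(fit))[1]
  p <- tryCatch(survival::cox.zph(fit)$table[term, "p"],
                error = function(e) NA_real_)
  list(schoenfeld_p = p,
       violation = if (is.na(p)) NA else p < threshold)
}

#' Reverse-causation sensitivity scan excluding early cases
#'
#' Removes cases diagnosed within `min_lead` years of baseline entirely,
#' then re-runs the scan on the reduced data with the same declared
#' multiplicity family size.
#'
#' @inheritParams pwas_scan
#' @param min_lead Minimum case lead time in years; default 2.
#' @return A `scan_result` data.frame.
#' @export
sensitivity_exclude_early <- function(cohort, matrix, min_lead = 2,
                                      covariates = baseline_covariates(),
                                      alpha = 0.05, family_size = NULL,
                                      ...) {
  check_columns(cohort, "lead_time")
  drop <- cohort$event == 1 & !is.na(cohort$lead_time) &
    cohort$lead_time < min_lead
  kept <- cohort[!drop, , drop = FALSE]
  if (sum(kept$event) == 0L) {
    stop("no cases remain after the early-diagnosis exclusion",
         call. = FALSE)
  }
  if (is.null(family_size)) family_size <- ncol(matrix)
  if (!is.null(rownames(matrix))) {
    matrix <- matrix[match(kept$participant_id, rownames(matrix)), ,
                     drop = FALSE]
  } else {
    matrix <- matrix[!drop, , drop = FALSE]
  }
  pwas_scan(kept, matrix, covariates = covariates, alpha = alpha,
            family_size = family_size, ...)
}

#' Sensitivity scan with additional adjustment covariates
#'
#' Re-runs the scan with the covariate set augmented by extra columns
#' (e.g. serum creatinine to address confounding by renal function).
#'
#' @inheritParams pwas_scan
#' @param extra_covariates Additional cohort columns to adjust for.
#' @return A `scan_result` data.frame.
#' @export
sensitivity_adjust <- function(cohort, matrix, extra_covariates,
                               covariates = baseline_covariates(), ...) {
  check_columns(cohort, extra_covariates)
  pwas_scan(cohort, matrix,
            covariates = unique(c(covariates, extra_covariates)), ...)
}
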