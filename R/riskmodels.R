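# Internal: assemble an analysis frame from cohort columns and protein
# columns; features may live in either.
build_model_frame <- function(cohort, matrix = NULL, features = character(0)) {
  df <- cohort
  from_matrix <- setdiff(features, names(cohort))
  if (length(from_matrix)) {
    if (is.null(matrix)) {
      stop("features not in cohort and no protein matrix supplied: ",
           paste(from_matrix, collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(from_matrix, colnames(matrix))
    if (length(missing)) {
      stop("unknown feature(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- matrix[match(cohort$participant_id, rownames(matrix)),
                from_matrix, drop = FALSE]
    df <- cbind(df, as.data.frame(m))
  }
  df
}

new_risk_model <- function(kind, fit, features, trace = NULL) {
  structure(list(kind = kind, fit = fit, features = features,
                 trace = trace),
            class = "risk_model")
}

#' Clinical risk model by bidirectional stepwise-AIC Cox regression
#'
#' Starts from the full Cox model over the candidate covariates and
#' performs bidirectional stepwise selection minimising AIC. The search is
#' deterministic given the data.
#'
#' @param cohort Cohort data.frame (derivation set).
#' @param candidates Candidate covariates; default the nine baseline ones.
#' @return A `risk_model` (kind "clinical"); an empty feature set is
#'   flagged via the `intercept_only` attribute.
#' @export
fit_clinical <- function(cohort, candidates = baseline_covariates()) {
  check_columns(cohort, c("followup_time", "event", candidates))
  full <- stats::as.formula(
    paste("survival::Surv(followup_time, event) ~",
          paste(candidates, collapse = " + ")))
  fit0 <- survival::coxph(full, data = cohort, ties = "efron",
                          model = TRUE)
  step <- suppressWarnings(
    MASS::stepAIC(fit0, direction = "both", trace = 0,
                  scope = list(lower = ~1, upper = full)))
  feats <- labels(stats::terms(step))
  model <- new_risk_model("clinical", step, feats, trace = step$anova)
  attr(model, "intercept_only") <- length(feats) == 0L
  model
}

#' Protein risk model by cross-validated LASSO-Cox selection
#'
#' Fits a LASSO-penalised Cox model over the FDR-significant proteins,
#' chooses the penalty minimising the cross-validated partial-likelihood
#' deviance, and refits the proteins with nonzero coefficients in an
#' unpenalised Cox model. If every coefficient is shrunk to zero at the
#' selected penalty, the first penalty down the path with a nonzero set is
#' used, with a warning.
#'
#' @param cohort Cohort data.frame (derivation set).
#' @param matrix Complete participants x proteins matrix.
#' @param fdr_hits Protein names entering the penalised model (e.g.
#'   BH q < 0.05 hits from [pwas_scan()]).
#' @param cv_folds Cross-validation folds; default 10.
#' @param seed Integer seed for the fold assignment.
#' @return A `risk_model` (kind "protein") whose `trace` holds the
#'   `cv.glmnet` object.
#' @export
fit_protein <- function(cohort, matrix, fdr_hits, cv_folds = 10, seed = 1L) {
  check_columns(cohort, c("followup_time", "event"))
  stopifnot(length(fdr_hits) >= 1)
  X <- matrix[match(cohort$participant_id, rownames(matrix)), fdr_hits,
              drop = FALSE]
  y <- survival::Surv(cohort$followup_time, cohort$event)
  if (length(fdr_hits) == 1L) {
    df <- build_model_frame(cohort, matrix, fdr_hits)
    fit <- survival::coxph(
      stats::as.formula(paste("survival::Surv(followup_time, event) ~",
                              fdr_hits)),
      data = df, ties = "efron", model = TRUE)
    return(new_risk_model("protein", fit, fdr_hits))
  }
  set_seed_if(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(X)))
  cv <- glmnet::cv.glmnet(X, y, family = "cox", type.measure = "deviance",
                          foldid = foldid)
  beta <- stats::coef(cv, s = "lambda.min")
  selected <- rownames(beta)[as.numeric(beta) != 0]
  if (!length(selected)) {
    warning("all coefficients zero at lambda.min; stepping down the path")
    path <- stats::coef(cv$glmnet.fit)
    nz <- colSums(path != 0)
    j <- which(nz > 0)[1]
    if (is.na(j)) stop("LASSO path contains no nonzero model", call. = FALSE)
    selected <- rownames(path)[path[, j] != 0]
  }
  df <- build_model_frame(cohort, matrix, selected)
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(followup_time, event) ~",
                            paste(selected, collapse = " + "))),
    data = df, ties = "efron", model = TRUE)
  new_risk_model("protein", fit, selected, trace = cv)
}

#' Combined clinical + protein model by stepwise-AIC over the union
#'
#' @param cohort Cohort data.frame (derivation set).
#' @param matrix Protein matrix supplying the protein features.
#' @param clinical,protein Fitted `risk_model`s whose selected features
#'   are pooled as candidates.
#' @return A `risk_model` (kind "combined").
#' @export
fit_combined <- function(cohort, matrix, clinical, protein) {
  feats <- unique(c(clinical$features, protein$features))
  if (!length(feats)) stop("both component models are empty", call. = FALSE)
  df <- build_model_frame(cohort, matrix, feats)
  full <- stats::as.formula(
    paste("survival::Surv(followup_time, event) ~",
          paste(feats, collapse = " + ")))
  fit0 <- survival::coxph(full, data = df, ties = "efron", model = TRUE)
  step <- suppressWarnings(
    MASS::stepAIC(fit0, direction = "both", trace = 0,
                  scope = list(lower = ~1, upper = full)))
  new_risk_model("combined", step, labels(stats::terms(step)),
                 trace = step$anova)
}

#' Linear predictor of a risk model on new data
#'
#' @param model A `risk_model`.
#' @param cohort Evaluation cohort.
#' @param matrix Protein matrix (if the model uses protein features).
#' @return Numeric linear predictor (risk score), higher = riskier.
#' @export
predict_lp <- function(model, cohort, matrix = NULL) {
  stopifnot(inherits(model, "risk_model"))
  if (!length(model$features)) return(rep(0, nrow(cohort)))
  df <- build_model_frame(cohort, matrix, model$features)
  as.numeric(stats::predict(model$fit, newdata = df, type = "lp"))
}

# Internal: censoring-distribution Kaplan-Meier evaluator G(t).
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t) {
    s <- summary(fit, times = pmax(t, 0), extend = TRUE)$surv
    pmax(s, 1e-10)
  }
}

#' Inverse-probability-of-censoring-weighted time-dependent AUC
#'
#' Cumulative-cases / dynamic-controls AUC at a horizon: cases are
#' participants with an observed event by the horizon, controls those
#' still event-free at the horizon; both are reweighted by the inverse of
#' the censoring-distribution Kaplan-Meier estimate. Undefined (NA) when
#' either group is empty.
#'
#' @param time,event Follow-up time and event indicator.
#' @param score Risk score (higher = riskier).
#' @param horizon Evaluation horizon in years.
#' @return AUC estimate in \[0, 1\], or `NA`.
#' @export
td_auc <- function(time, event, score, horizon) {
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  if (!any(case) || !any(ctrl)) return(NA_real_)
  G <- censoring_km(time, event)
  w_case <- 1 / G(pmax(time[case] - 1e-10, 0))
  w_ctrl <- rep(1 / G(horizon), sum(ctrl))
  sc <- score[case]; sn <- score[ctrl]
  num <- 0; den <- 0
  for (i in seq_along(sc)) {
    gt <- sum(w_ctrl[sc[i] > sn])
    eq <- sum(w_ctrl[sc[i] == sn])
    num <- num + w_case[i] * (gt + 0.5 * eq)
    den <- den + w_case[i] * sum(w_ctrl)
  }
  num / den
}

# Internal: predicted absolute risk by a horizon from a fitted coxph,
# 1 - exp(-H0(h) e^lp) with the Breslow baseline from the training data.
predicted_risk <- function(model, lp, horizon) {
  bh <- survival::basehaz(model$fit, centered = TRUE)
  H0 <- if (any(bh$time <= horizon)) max(bh$hazard[bh$time <= horizon]) else 0
  1 - exp(-H0 * exp(lp))
}

#' Integrated discrimination improvement at a horizon
#'
#' Difference in discrimination slope (mean predicted risk among events by
#' the horizon minus mean among those event-free at the horizon, both
#' IPCW-reweighted) between a model and a reference. Identically zero when
#' the two risk vectors coincide, and antisymmetric under swapping them.
#'
#' @param risk_new,risk_ref Predicted risks at the horizon under the two
#'   models.
#' @param time,event Follow-up time and event indicator.
#' @param horizon Horizon in years.
#' @return List with `idi` and the two discrimination slopes.
#' @export
idi_at_horizon <- function(risk_new, risk_ref, time, event, horizon) {
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  if (!any(case) || !any(ctrl)) {
    return(list(idi = NA_real_, slope_new = NA_real_, slope_ref = NA_real_))
  }
  G <- censoring_km(time, event)
  w_case <- 1 / G(pmax(time[case] - 1e-10, 0))
  slope <- function(risk) {
    stats::weighted.mean(risk[case], w_case) - mean(risk[ctrl])
  }
  s_new <- slope(risk_new); s_ref <- slope(risk_ref)
  list(idi = s_new - s_ref, slope_new = s_new, slope_ref = s_ref)
}

# Internal: IPCW Youden-optimal score cutoff at a horizon.
youden_cutoff <- function(time, event, score, horizon) {
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  if (!any(case) || !any(ctrl)) return(NA_real_)
  G <- censoring_km(time, event)
  w_case <- 1 / G(pmax(time[case] - 1e-10, 0))
  cuts <- sort(unique(score))
  youden <- vapply(cuts, function(cc) {
    sens <- sum(w_case[score[case] > cc]) / sum(w_case)
    spec <- mean(score[ctrl] <= cc)
    sens + spec - 1
  }, numeric(1))
  cuts[which.max(youden)]
}

#' Evaluate a frozen risk model on an evaluation split
#'
#' Computes Harrell's C-index with a 95% CI, IPCW time-dependent AUC over
#' the horizon grid, the IDI versus a reference model at the IDI horizon,
#' a paired-bootstrap p-value for the C-index difference versus the
#' reference, the Youden-optimal cutoff at the IDI horizon, and the
#' log-rank test for the dichotomised score. The model is never refitted
#' on the evaluation data.
#'
#' @param model A fitted `risk_model` (frozen).
#' @param cohort Evaluation cohort.
#' @param matrix Protein matrix for protein features.
#' @param horizons Horizon grid in years; default 2..10. Horizons beyond
#'   the maximum follow-up are dropped with a warning.
#' @param reference Optional reference `risk_model` for IDI and C-index
#'   comparison.
#' @param idi_horizon Horizon for IDI and the Youden cutoff; default 10.
#' @param n_boot Paired-bootstrap resamples for the C-index comparison;
#'   default 500.
#' @param seed Integer seed for the bootstrap.
#' @param cutoff Optional pre-computed score cutoff (e.g. derived on the
#'   derivation split) applied unchanged; default computes it here.
#' @return A list of class `model_eval`.
#' @export
evaluate_risk_model <- function(model, cohort, matrix = NULL,
                                horizons = 2:10, reference = NULL,
                                idi_horizon = 10, n_boot = 500, seed = 1L,
                                cutoff = NULL) {
  stopifnot(inherits(model, "risk_model"))
  time <- cohort$followup_time; event <- cohort$event
  lp <- predict_lp(model, cohort, matrix)

  drop <- horizons > max(time)
  if (any(drop)) {
    warning("dropping horizon(s) beyond max follow-up: ",
            paste(horizons[drop], collapse = ", "))
    horizons <- horizons[!drop]
  }

  conc <- survival::concordance(
    survival::Surv(time, event) ~ lp, reverse = TRUE)
  c_se <- sqrt(conc$var)
  auc <- vapply(horizons, function(h) td_auc(time, event, lp, h),
                numeric(1))
  names(auc) <- horizons

  idi <- NULL; cindex_p <- NA_real_; idi_p <- NA_real_
  if (!is.null(reference)) {
    lp_ref <- predict_lp(reference, cohort, matrix)
    r_new <- predicted_risk(model, lp, idi_horizon)
    r_ref <- predicted_risk(reference, lp_ref, idi_horizon)
    idi <- idi_at_horizon(r_new, r_ref, time, event, idi_horizon)
    set_seed_if(seed)
    diffs <- idis <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(time), replace = TRUE)
      cb <- tryCatch(
        survival::concordance(
          survival::Surv(time[idx], event[idx]) ~ lp[idx],
          reverse = TRUE)$concordance -
          survival::concordance(
            survival::Surv(time[idx], event[idx]) ~ lp_ref[idx],
            reverse = TRUE)$concordance,
        error = function(e) NA_real_)
      diffs[b] <- cb
      ib <- idi_at_horizon(r_new[idx], r_ref[idx], time[idx], event[idx],
                           idi_horizon)$idi
      idis[b] <- ib
    }
    diffs <- diffs[is.finite(diffs)]
    if (length(diffs) > 10 && stats::sd(diffs) > 0) {
      cindex_p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
      cindex_p <- min(max(cindex_p, 1 / length(diffs)), 1)
    }
    idis <- idis[is.finite(idis)]
    if (length(idis) > 10 && stats::sd(idis) > 0) {
      idi_p <- 2 * min(mean(idis <= 0), mean(idis >= 0))
      idi_p <- min(max(idi_p, 1 / length(idis)), 1)
    }
  }

  if (is.null(cutoff)) cutoff <- youden_cutoff(time, event, lp, idi_horizon)
  logrank_p <- NA_real_
  if (is.finite(cutoff) && length(unique(lp > cutoff)) == 2L) {
    sd_ <- survival::survdiff(
      survival::Surv(time, event) ~ I(lp > cutoff))
    logrank_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  }

  structure(list(
    kind = model$kind,
    c_index = unname(conc$concordance),
    c_index_ci = unname(conc$concordance +
                          c(-1, 1) * stats::qnorm(0.975) * c_se),
    c_index_se = c_se,
    td_auc = auc,
    idi = if (is.null(idi)) NA_real_ else idi$idi,
    idi_p = idi_p,
    c_index_comparison_p = cindex_p,
    km_cutoff = cutoff,
    logrank_p = logrank_p,
    n = length(time), n_events = sum(event)
  ), class = "model_eval")
}

#' Discrimination metrics for an arbitrary risk score
#'
#' Evaluates a raw score vector (e.g. the generator's true linear
#' predictor, or a random score) without any model fitting: Harrell's
#' C-index with CI and the IPCW time-dependent AUC over the horizon grid.
#'
#' @param score Numeric risk score, higher = riskier.
#' @param cohort Cohort with `followup_time` and `event`.
#' @param horizons Horizon grid; default 2..10 years.
#' @return A list with `c_index`, `c_index_ci`, `td_auc`.
#' @export
evaluate_score <- function(score, cohort, horizons = 2:10) {
  time <- cohort$followup_time; event <- cohort$event
  stopifnot(length(score) == length(time))
  horizons <- horizons[horizons <= max(time)]
  conc <- survival::concordance(
    survival::Surv(time, event) ~ score, reverse = TRUE)
  auc <- vapply(horizons, function(h) td_auc(time, event, score, h),
                numeric(1))
  names(auc) <- horizons
  list(c_index = unname(conc$concordance),
       c_index_ci = unname(conc$concordance +
                             c(-1, 1) * stats::qnorm(0.975) *
                             sqrt(conc$var)),
       td_auc = auc)
}

#' Single-marker evaluation
#'
#' Fits a univariate Cox model on one protein in the derivation split and
#' evaluates it (frozen) on the evaluation split, reporting the full set
#' of discrimination metrics including the AUC-by-horizon trend.
#'
#' @param protein Protein name.
#' @param cohort Derivation cohort.
#' @param matrix Derivation protein matrix.
#' @param eval_cohort,eval_matrix Evaluation split; default the derivation
#'   data itself.
#' @param ... Passed to [evaluate_risk_model()].
#' @return A list with `model` (the `risk_model`) and `eval`
#'   (the `model_eval`).
#' @export
evaluate_single_marker <- function(protein, cohort, matrix,
                                   eval_cohort = cohort,
                                   eval_matrix = matrix, ...) {
  if (!protein %in% colnames(matrix)) {
    stop("protein not present: ", protein, call. = FALSE)
  }
  df <- build_model_frame(cohort, matrix, protein)
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(followup_time, event) ~",
                            protein)),
    data = df, ties = "efron", model = TRUE)
  model <- new_risk_model("single", fit, protein)
  list(model = model,
       eval = evaluate_risk_model(model, eval_cohort, eval_matrix, ...))
}
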