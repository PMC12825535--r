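#' Closed-form four-way effect components for a normal mediator
#'
#' Computes the total effect and its four components — controlled direct
#' effect (CDE), reference interaction (INTref), mediated interaction
#' (INTmed) and pure indirect effect (PIE) — on the excess relative risk
#' scale, for an outcome with log-linear (rare-outcome Cox) hazard
#' `g(a, m) = exp(theta1 a + theta2 m + theta3 a m)` and a normal mediator
#' `M | A = a ~ N(beta0 + beta1 a + beta2c, sigma2)` (with `beta2c` the
#' covariate contribution at the chosen reference level). The normal
#' moment-generating function gives the closed form
#' `Q(a, a') = exp(theta1 a) * exp((theta2 + theta3 a) mu(a') +
#' (theta2 + theta3 a)^2 sigma2 / 2)` for the expected relative hazard
#' under exposure `a` and the mediator distribution of `a'`; components
#' are contrasts of `Q` and `g` normalised by `Q(a*, a*)` and sum to the
#' total effect exactly.
#'
#' @param beta0,beta1,beta2c Mediator-model intercept, exposure slope and
#'   covariate contribution evaluated at the reference covariate level.
#' @param sigma2 Mediator residual variance (> 0).
#' @param theta1,theta2,theta3 Outcome-model log-hazard coefficients for
#'   exposure, mediator and their product.
#' @param a,a_star Index and reference exposure levels.
#' @param m_star Reference mediator level for the CDE.
#' @return A list with `te`, `cde`, `int_ref`, `int_med`, `pie`,
#'   `proportion_mediated` (PIE/TE) and `proportion_mediated_total`
#'   ((PIE + INTmed)/TE).
#' @export
fourway_components <- function(beta0, beta1, beta2c = 0, sigma2,
                               theta1, theta2, theta3,
                               a = 1, a_star = 0, m_star = 0) {
  stopifnot(sigma2 > 0, a != a_star)
  mu <- function(x) beta0 + beta1 * x + beta2c
  Q <- function(x, xp) {
    th <- theta2 + theta3 * x
    exp(theta1 * x) * exp(th * mu(xp) + 0.5 * th^2 * sigma2)
  }
  g <- function(x, m) exp(theta1 * x + theta2 * m + theta3 * x * m)
  D <- Q(a_star, a_star)
  te <- (Q(a, a) - Q(a_star, a_star)) / D
  cde <- (g(a, m_star) - g(a_star, m_star)) / D
  int_ref <- (Q(a, a_star) - Q(a_star, a_star) -
                g(a, m_star) + g(a_star, m_star)) / D
  int_med <- (Q(a, a) - Q(a_star, a) - Q(a, a_star) + Q(a_star, a_star)) / D
  pie <- (Q(a_star, a) - Q(a_star, a_star)) / D
  prop <- if (abs(te) < .Machine$double.eps) NA_real_ else pie / te
  prop_tot <- if (abs(te) < .Machine$double.eps) NA_real_ else
    (pie + int_med) / te
  list(te = te, cde = cde, int_ref = int_ref, int_med = int_med, pie = pie,
       proportion_mediated = prop, proportion_mediated_total = prop_tot)
}

# Internal: resolve the exposure column to a numeric vector. Continuous
# exposures are standardized to mean 0, SD 1; binary ones are coded 0/1
# (factor reference level = 0).
resolve_exposure <- function(cohort, exposure, kind) {
  x <- cohort[[exposure]]
  if (kind == "continuous") {
    # an already 0/1-valued exposure is left on its natural scale, so the
    # continuous and binary paths agree on such data
    if (all(x %in% c(0, 1))) as.numeric(x) else as.numeric(scale(x))
  } else {
    if (is.factor(x)) as.numeric(x != levels(x)[1]) else as.numeric(x != 0)
  }
}

#' Fit the mediator and outcome models of a mediation pair
#'
#' Ordinary least squares for the mediator model
#' `M = beta0 + beta1 A + beta2' C + eps` and a Cox proportional-hazards
#' outcome model with an exposure-by-mediator product term,
#' `log h = theta1 A + theta2 M + theta3 A M + theta4' C`. Continuous
#' exposures are standardized; binary ones coded 0/1. A warning is issued
#' if the event fraction exceeds 5%, where the rare-outcome hazard-ratio /
#' relative-risk approximation weakens.
#'
#' @param cohort Cohort data.frame with `followup_time`, `event`, the
#'   exposure and the covariates.
#' @param exposure Exposure column name (e.g. `"bmi"`, `"smoking"`).
#' @param mediator Numeric mediator vector aligned with `cohort`, or a
#'   protein name to be looked up in `matrix`.
#' @param covariates Adjustment covariates; the exposure itself is removed
#'   from this set automatically.
#' @param exposure_kind "continuous" or "binary"; default guesses
#'   continuous for numeric columns with more than two levels.
#' @param matrix Optional participants x proteins matrix for name lookup.
#' @return An object of class `mediation_models` holding both fits, the
#'   extracted coefficients, `sigma2`, and the analysis data (for
#'   bootstrap refits).
#' @export
fit_mediation_models <- function(cohort, exposure, mediator,
                                 covariates = baseline_covariates(),
                                 exposure_kind = NULL, matrix = NULL) {
  check_columns(cohort, c("followup_time", "event", exposure))
  if (is.character(mediator) && length(mediator) == 1L) {
    if (is.null(matrix) || !mediator %in% colnames(matrix)) {
      stop("mediator '", mediator, "' not found in the protein matrix",
           call. = FALSE)
    }
    med_name <- mediator
    mediator <- matrix[match(cohort$participant_id, rownames(matrix)),
                       mediator]
  } else {
    med_name <- "mediator"
  }
  stopifnot(length(mediator) == nrow(cohort))
  if (stats::sd(mediator) == 0) stop("mediator is constant", call. = FALSE)
  if (is.null(exposure_kind)) {
    x <- cohort[[exposure]]
    exposure_kind <- if (is.numeric(x) && length(unique(x)) > 2L) {
      "continuous"
    } else {
      "binary"
    }
  }
  exposure_kind <- match.arg(exposure_kind, c("continuous", "binary"))
  covariates <- setdiff(covariates, exposure)
  ev_frac <- mean(cohort$event)
  if (ev_frac > 0.05) {
    warning(sprintf(paste("event fraction %.1f%% exceeds 5%%: the",
                          "hazard-ratio ~ relative-risk approximation",
                          "may be poor"), 100 * ev_frac))
  }

  dat <- cohort[, c("followup_time", "event", covariates), drop = FALSE]
  dat$.a <- resolve_exposure(cohort, exposure, exposure_kind)
  dat$.m <- as.numeric(mediator)

  rhs_c <- if (length(covariates)) {
    paste("+", paste(covariates, collapse = " + "))
  } else ""
  med_fit <- stats::lm(stats::as.formula(paste(".m ~ .a", rhs_c)),
                       data = dat)
  out_fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(followup_time, event) ~",
                            ".a * .m", rhs_c)),
    data = dat, ties = "efron", x = TRUE)
  bm <- stats::coef(med_fit)
  bo <- stats::coef(out_fit)
  if (anyNA(bm) || anyNA(bo)) {
    stop("model fitting failed (NA coefficients)", call. = FALSE)
  }
  structure(list(
    mediator_model = med_fit,
    outcome_model = out_fit,
    beta0 = unname(bm["(Intercept)"]),
    beta1 = unname(bm[".a"]),
    sigma2 = sum(stats::residuals(med_fit)^2) / med_fit$df.residual,
    theta1 = unname(bo[".a"]),
    theta2 = unname(bo[".m"]),
    theta3 = unname(bo[".a:.m"]),
    exposure = exposure, exposure_kind = exposure_kind,
    mediator_name = med_name,
    covariates = covariates,
    data = dat
  ), class = "mediation_models")
}

# Internal: covariate contribution beta2' c of an lm mediator model at a
# reference covariate row (numeric -> mean, factor -> modal category).
# The reference row on the design-matrix scale is attached as attribute
# "ref_row" so bootstrap resamples can reuse it.
covariate_contribution <- function(med_fit, dat, covariates,
                                   covariate_level = NULL) {
  if (!length(covariates)) return(0)
  if (is.null(covariate_level)) {
    covariate_level <- dat[1, covariates, drop = FALSE]
    for (cc in covariates) {
      v <- dat[[cc]]
      covariate_level[[cc]] <- if (is.numeric(v)) {
        mean(v)
      } else {
        names(sort(table(v), decreasing = TRUE))[1]
      }
    }
  }
  covariate_level$.a <- 0
  covariate_level$.m <- 0
  tt <- stats::delete.response(stats::terms(med_fit))
  mf <- stats::model.frame(tt, covariate_level, xlev = med_fit$xlevels)
  X <- stats::model.matrix(tt, mf, contrasts.arg = med_fit$contrasts)
  cf <- stats::coef(med_fit)
  cov_cols <- setdiff(colnames(X), c("(Intercept)", ".a"))
  out <- sum(cf[cov_cols] * X[1, cov_cols])
  attr(out, "ref_row") <- X[1, ]
  out
}

# Internal: components from a fitted pair at fixed reference settings.
components_from_fit <- function(models, a, a_star, m_star, beta2c) {
  fourway_components(beta0 = models$beta0, beta1 = models$beta1,
                     beta2c = beta2c, sigma2 = models$sigma2,
                     theta1 = models$theta1, theta2 = models$theta2,
                     theta3 = models$theta3,
                     a = a, a_star = a_star, m_star = m_star)
}

#' Four-way decomposition of a fitted mediation model pair
#'
#' Evaluates the excess-relative-risk four-way decomposition
#' (TE = CDE + INTref + INTmed + PIE) at the requested exposure contrast,
#' with uncertainty from a seeded nonparametric bootstrap that refits both
#' models on each resample. Mediation is called significant when both the
#' TE and the PIE p-values fall below 0.05.
#'
#' @param models A `mediation_models` pair from [fit_mediation_models()].
#' @param a,a_star Index and reference exposure levels; defaults 1 and 0.
#' @param m_star Reference mediator level for the CDE; default the
#'   marginal sample mean of the mediator.
#' @param covariate_level Optional one-row data.frame of covariate values
#'   at which the mediator mean is evaluated; default numeric means and
#'   modal categories.
#' @param ci "bootstrap" (percentile intervals, default) or "none".
#' @param n_boot Bootstrap resamples; default 500.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `fourway_result`: a list with the point
#'   estimates (`te`, `cde`, `int_ref`, `int_med`, `pie`), mediation
#'   proportions, and — when bootstrapped — per-component `se`, `ci_low`,
#'   `ci_high`, `p`, plus the `significant` flag.
#' @export
fourway_decompose <- function(models, a = 1, a_star = 0, m_star = NULL,
                              covariate_level = NULL,
                              ci = c("bootstrap", "none"), n_boot = 500,
                              seed = 1L) {
  stopifnot(inherits(models, "mediation_models"))
  ci <- match.arg(ci)
  if (a == a_star) stop("a and a_star must differ", call. = FALSE)
  if (is.null(m_star)) m_star <- mean(models$data$.m)
  beta2c <- covariate_contribution(models$mediator_model, models$data,
                                   models$covariates, covariate_level)
  est <- components_from_fit(models, a, a_star, m_star, as.numeric(beta2c))
  comp_names <- c("te", "cde", "int_ref", "int_med", "pie")
  out <- c(est, list(a = a, a_star = a_star, m_star = m_star,
                     mediator = models$mediator_name,
                     exposure = models$exposure))

  if (ci == "bootstrap") {
    set_seed_if(seed)
    dat <- models$data
    n <- nrow(dat)
    # precomputed design matrices: resampling rows wholesale keeps the
    # factor coding and the product term consistent, and lets the
    # resamples refit through the fast matrix interfaces
    Xm <- stats::model.matrix(models$mediator_model)
    ym <- dat$.m
    Xo <- models$outcome_model[["x"]]
    yo <- survival::Surv(dat$followup_time, dat$event)
    ctrl <- survival::coxph.control()
    # reference covariate row on the mediator design scale (fixed at the
    # point-estimate level across resamples)
    cov_cols <- setdiff(colnames(Xm), c("(Intercept)", ".a"))
    ref_x <- attr(beta2c, "ref_row")
    boot <- matrix(NA_real_, n_boot, length(comp_names),
                   dimnames = list(NULL, comp_names))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      rep_est <- tryCatch({
        mf <- stats::lm.fit(Xm[idx, , drop = FALSE], ym[idx])
        bm <- mf$coefficients
        sigma2_b <- sum(mf$residuals^2) / (n - mf$rank)
        of <- suppressWarnings(survival::coxph.fit(
          Xo[idx, , drop = FALSE], yo[idx, ], strata = NULL,
          offset = NULL, init = NULL, control = ctrl, weights = NULL,
          method = "efron", rownames = NULL, resid = FALSE))
        bo <- of$coefficients
        names(bo) <- colnames(Xo)
        mb <- list(beta0 = unname(bm["(Intercept)"]),
                   beta1 = unname(bm[".a"]),
                   sigma2 = sigma2_b,
                   theta1 = unname(bo[".a"]), theta2 = unname(bo[".m"]),
                   theta3 = unname(bo[".a:.m"]))
        b2c <- if (length(cov_cols)) {
          sum(bm[cov_cols] * ref_x[cov_cols])
        } else 0
        components_from_fit(mb, a, a_star, m_star, b2c)
      }, error = function(e) NULL)
      if (!is.null(rep_est) &&
          all(is.finite(unlist(rep_est[comp_names])))) {
        boot[b, ] <- unlist(rep_est[comp_names])
      }
    }
    boot <- boot[stats::complete.cases(boot), , drop = FALSE]
    if (nrow(boot) < max(20, n_boot / 2)) {
      warning("more than half of the bootstrap refits failed")
    }
    se <- apply(boot, 2, stats::sd)
    ci_low <- apply(boot, 2, stats::quantile, probs = 0.025)
    ci_high <- apply(boot, 2, stats::quantile, probs = 0.975)
    pt <- unlist(est[comp_names])
    p <- 2 * stats::pnorm(-abs(pt / se))
    prop_boot <- ifelse(abs(boot[, "te"]) > .Machine$double.eps,
                        boot[, "pie"] / boot[, "te"], NA_real_)
    out$se <- se
    out$ci_low <- ci_low
    out$ci_high <- ci_high
    out$p <- p
    out$proportion_ci <- stats::quantile(prop_boot, c(0.025, 0.975),
                                         na.rm = TRUE)
    out$n_boot_ok <- nrow(boot)
    out$significant <- is.finite(p["te"]) && is.finite(p["pie"]) &&
      p["te"] < 0.05 && p["pie"] < 0.05
  }
  class(out) <- "fourway_result"
  out
}

#' Per-protein exposure associations (mediation screening leg)
#'
#' Linear regression of each protein on the exposure plus covariates;
#' returns the Wald p-value (and estimate) of the exposure coefficient.
#'
#' @inheritParams fit_mediation_models
#' @param matrix Complete participants x proteins matrix.
#' @return data.frame with `protein`, `estimate`, `p`.
#' @export
exposure_associations <- function(cohort, matrix, exposure,
                                  covariates = baseline_covariates(),
                                  exposure_kind = NULL) {
  check_columns(cohort, exposure)
  if (is.null(exposure_kind)) {
    x <- cohort[[exposure]]
    exposure_kind <- if (is.numeric(x) && length(unique(x)) > 2L) {
      "continuous"
    } else "binary"
  }
  covariates <- setdiff(covariates, exposure)
  a <- resolve_exposure(cohort, exposure, exposure_kind)
  X <- stats::model.matrix(
    stats::as.formula(paste("~ a",
                            if (length(covariates)) {
                              paste("+", paste(covariates, collapse = " + "))
                            } else "")),
    data = cbind(cohort, a = a))
  matrix <- matrix[match(cohort$participant_id, rownames(matrix)), ,
                   drop = FALSE]
  fit <- stats::lm.fit(X, matrix)
  rss <- colSums(fit$residuals^2)
  df <- nrow(X) - ncol(X)
  XtXinv_aa <- chol2inv(chol(crossprod(X)))[2, 2]
  est <- fit$coefficients["a", ]
  se <- sqrt(rss / df * XtXinv_aa)
  data.frame(protein = colnames(matrix), estimate = est, p =
               2 * stats::pt(-abs(est / se), df),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen candidate mediators on both legs
#'
#' Retains proteins significant both in the exposure -> protein linear leg
#' and the protein -> outcome Cox leg, at `alpha` on each leg.
#'
#' @param exposure_assoc data.frame from [exposure_associations()].
#' @param scan A `scan_result` from [pwas_scan()] (or any data.frame with
#'   `protein` and `p`).
#' @param alpha Per-leg significance level; default 0.05.
#' @return Character vector of candidate mediator protein names.
#' @export
screen_mediators <- function(exposure_assoc, scan, alpha = 0.05) {
  leg1 <- exposure_assoc$protein[!is.na(exposure_assoc$p) &
                                   exposure_assoc$p < alpha]
  leg2 <- scan$protein[!is.na(scan$p) & scan$p < alpha]
  intersect(leg1, leg2)
}

#' Principal-component aggregation of protein mediators
#'
#' Drops mediators whose PIE and CDE disagree in sign, standardizes the
#' remaining columns, and extracts principal components, retaining those
#' with eigenvalue > 1 on the correlation scale (Kaiser criterion; if none
#' qualifies the first component is kept with a warning). Scores are
#' standardized to SD 1.
#'
#' @param matrix Participants x proteins matrix containing the mediators.
#' @param fourway Named list of `fourway_result`s (names = proteins) used
#'   for the opposing-sign exclusion; optional if `mediators` is given.
#' @param mediators Optional character vector of mediator columns to use
#'   directly (bypasses the sign exclusion).
#' @return A list with `scores` (participants x retained components, SD 1),
#'   `loadings`, `eigenvalues`, `retained` (count) and `mediators` (the
#'   columns used).
#' @export
pca_aggregate <- function(matrix, fourway = NULL, mediators = NULL) {
  if (is.null(mediators)) {
    stopifnot(!is.null(fourway))
    keep <- vapply(fourway, function(f) sign(f$pie) == sign(f$cde),
                   logical(1))
    mediators <- names(fourway)[keep]
  }
  if (length(mediators) < 2L) {
    stop("need at least 2 mediators after the opposing-sign exclusion",
         call. = FALSE)
  }
  X <- scale(matrix[, mediators, drop = FALSE])
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  retained <- which(ev > 1)
  if (!length(retained)) {
    warning("no component passes the Kaiser criterion; retaining the first")
    retained <- 1L
  }
  scores <- scale(pc$x[, retained, drop = FALSE])
  rownames(scores) <- rownames(matrix)
  list(scores = scores,
       loadings = pc$rotation[, retained, drop = FALSE],
       eigenvalues = ev, retained = length(retained),
       mediators = mediators)
}

#' Four-way mediation through principal-component scores
#'
#' Runs the decomposition with each retained component score as the
#' mediator. The combined proportion mediated is the PIE-based proportion
#' for a single component; with several orthogonal components it is the
#' sum of the per-component proportions, flagged as an approximation
#' (the decomposition is nonlinear).
#'
#' @inheritParams fit_mediation_models
#' @param scores Score matrix from [pca_aggregate()].
#' @param ... Passed to [fourway_decompose()] (e.g. `ci`, `n_boot`, `seed`).
#' @return A list with `components` (one `fourway_result` per score),
#'   `combined_proportion`, and `approximate` (TRUE when summed over
#'   more than one component).
#' @export
mediate_via_pca <- function(cohort, scores, exposure,
                            covariates = baseline_covariates(),
                            exposure_kind = NULL, ...) {
  res <- lapply(seq_len(ncol(scores)), function(j) {
    models <- fit_mediation_models(cohort, exposure, scores[, j],
                                   covariates = covariates,
                                   exposure_kind = exposure_kind)
    fourway_decompose(models, ...)
  })
  names(res) <- colnames(scores)
  props <- vapply(res, `[[`, numeric(1), "proportion_mediated")
  list(components = res,
       combined_proportion = sum(props),
       approximate = ncol(scores) > 1L)
}
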