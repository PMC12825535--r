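#' Configuration for the synthetic cohort generator
#'
#' Defines a seeded synthetic prospective cohort with an approximately
#' standard-normal NPX protein matrix, a rare proportional-hazards outcome,
#' planted lead-time trajectory archetypes for case proteins, and an
#' exposure -> mediator -> hazard mediation structure. Defaults reflect a
#' biobank-style population: cumulative incidence 0.34% over a median
#' follow-up of 11.76 years.
#'
#' @param n_participants Number of participants.
#' @param n_proteins Number of NPX protein variables.
#' @param event_rate Target cumulative incidence in (0, 1).
#' @param followup_median Median administrative follow-up, years.
#' @param missing_rate Per-cell MCAR missingness probability in \[0, 0.5\].
#' @param archetype_assignments Named integer vector mapping protein names
#'   to archetype ids 1..4; unnamed proteins carry no trajectory signal.
#' @param signal_log_hr Named numeric vector of true log hazard ratios per
#'   SD NPX; unnamed proteins are null.
#' @param mediation_spec Optional list describing the mediation structure:
#'   `exposure` ("bmi" for the standardized continuous exposure or
#'   "smoking" for the binary one), `beta1` (named numeric, exposure effect
#'   on each mediator protein in NPX SD per exposure unit), and scalar
#'   log-hazard coefficients `theta1` (exposure), `theta2` (mediator),
#'   `theta3` (exposure x mediator interaction).
#' @param prior_cancer_rate Fraction flagged with prior cancer (for
#'   exercising the exclusion cascade); default 0.
#' @param covariate_missing_rate Fraction of participants with one missing
#'   covariate; default 0.
#' @param seed Integer seed; fully determines the generated data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 5000,
                       n_proteins = 100,
                       event_rate = 0.0034,
                       followup_median = 11.76,
                       missing_rate = 0,
                       archetype_assignments = integer(0),
                       signal_log_hr = numeric(0),
                       mediation_spec = NULL,
                       prior_cancer_rate = 0,
                       covariate_missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_participants >= 2, n_proteins >= 1)
  if (!(event_rate > 0 && event_rate < 1)) {
    stop("event_rate must lie in (0, 1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 0.5) {
    stop("missing_rate must lie in [0, 0.5]", call. = FALSE)
  }
  proteins <- sprintf("PROT%04d", seq_len(n_proteins))
  bad <- setdiff(names(archetype_assignments), proteins)
  if (length(bad)) {
    stop("archetype_assignments names unknown protein(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(archetype_assignments) &&
      !all(archetype_assignments %in% 1:4)) {
    stop("archetype ids must be in 1..4", call. = FALSE)
  }
  bad <- setdiff(names(signal_log_hr), proteins)
  if (length(bad)) {
    stop("signal_log_hr names unknown protein(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(mediation_spec)) {
    stopifnot(is.list(mediation_spec))
    if (!mediation_spec$exposure %in% c("bmi", "smoking")) {
      stop("mediation exposure must be 'bmi' or 'smoking'", call. = FALSE)
    }
    bad <- setdiff(names(mediation_spec$beta1), proteins)
    if (length(bad)) {
      stop("mediation_spec names unknown mediator protein(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_proteins = as.integer(n_proteins),
    proteins = proteins,
    event_rate = event_rate,
    followup_median = followup_median,
    missing_rate = missing_rate,
    archetype_assignments = archetype_assignments,
    signal_log_hr = signal_log_hr,
    mediation_spec = mediation_spec,
    prior_cancer_rate = prior_cancer_rate,
    covariate_missing_rate = covariate_missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Internal: calibrate the exponential baseline hazard by bisection so the
# expected cumulative incidence, given realized linear predictors and
# administrative censoring times, matches the target.
calibrate_lambda0 <- function(lp, censor_time, target) {
  f <- function(log_l0) {
    mean(1 - exp(-exp(log_l0 + lp) * censor_time)) - target
  }
  stats::uniroot(f, lower = -40, upper = 10, tol = 1e-12)$root |> exp()
}

#' Simulate a synthetic pre-diagnostic proteomics cohort
#'
#' Draws covariates, an NPX matrix, and proportional-hazards event times
#' whose linear predictor includes declared signal proteins, the mediation
#' exposure and mediator proteins. Case proteins assigned a trajectory
#' archetype have their NPX expectation shifted by
#' [archetype_shape()] evaluated at the case's lead time, so baseline-only
#' measurements indexed by lead time trace the archetype curve. An MCAR
#' mask is applied last. A ground-truth record (true log hazard ratios,
#' archetype labels, mediation parameters with their derived four-way
#' components, and the generator's internal hazard record) supports
#' recovery testing.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `cohort`
#'   (data.frame), `proteins` (numeric matrix, participants x proteins,
#'   `NA` for missing), and `truth` (list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  p <- config$n_proteins

  cohort <- data.frame(
    participant_id = sprintf("ID%06d", seq_len(n)),
    age = stats::runif(n, 40, 70),
    sex = factor(ifelse(stats::rbinom(n, 1, 0.47) == 1, "male", "female"),
                 levels = c("female", "male")),
    ethnicity = factor(ifelse(stats::rbinom(n, 1, 0.94) == 1, "white", "other"),
                       levels = c("white", "other")),
    deprivation_index = stats::rnorm(n, 0, 3),
    smoking = factor(ifelse(stats::rbinom(n, 1, 0.45) == 1, "ever", "never"),
                     levels = c("never", "ever")),
    alcohol = factor(sample(c("never", "moderate", "frequent"), n,
                            replace = TRUE, prob = c(0.1, 0.6, 0.3)),
                     levels = c("never", "moderate", "frequent")),
    bmi = stats::rnorm(n, 27, 4.5),
    hypertension = stats::rbinom(n, 1, 0.27),
    diabetes = stats::rbinom(n, 1, 0.05),
    prior_cancer = stats::rbinom(n, 1, config$prior_cancer_rate),
    creatinine = stats::rnorm(n, 70, 15),
    stringsAsFactors = FALSE
  )

  npx <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(cohort$participant_id, config$proteins))

  # mediator structure: M = beta1 * A + N(0,1); sigma2 = 1 by construction
  med <- config$mediation_spec
  lp_med <- numeric(n)
  if (!is.null(med)) {
    a_vec <- if (med$exposure == "bmi") {
      as.numeric(scale(cohort$bmi))
    } else {
      as.numeric(cohort$smoking == "ever")
    }
    for (m in names(med$beta1)) {
      npx[, m] <- med$beta1[[m]] * a_vec + stats::rnorm(n)
      lp_med <- lp_med + med$theta2 * npx[, m] +
        med$theta3 * a_vec * npx[, m]
    }
    lp_med <- lp_med + med$theta1 * a_vec
  }

  lp_sig <- numeric(n)
  for (s in names(config$signal_log_hr)) {
    lp_sig <- lp_sig + config$signal_log_hr[[s]] * npx[, s]
  }
  lp <- lp_sig + lp_med

  # administrative censoring window reproduces the biobank-style follow-up
  # spread (median ~ followup_median, IQR ~ 1.3 y)
  censor_time <- stats::runif(n, config$followup_median - 1.26,
                              config$followup_median + 1.26)
  lambda0 <- calibrate_lambda0(lp, censor_time, config$event_rate)
  event_time <- stats::rexp(n, rate = 1) / (lambda0 * exp(lp))
  event <- as.integer(event_time <= censor_time)
  followup_time <- pmin(event_time, censor_time)
  lead_time <- ifelse(event == 1, followup_time, NA_real_)
  cohort$followup_time <- followup_time
  cohort$event <- event
  cohort$lead_time <- lead_time

  # case trajectory signal: shift case NPX by the archetype shape at the
  # case's lead time (controls carry shape == 0)
  arch <- config$archetype_assignments
  cases <- which(event == 1)
  if (length(arch) && length(cases)) {
    for (pr in names(arch)) {
      lt <- pmin(lead_time[cases], 15)
      npx[cases, pr] <- npx[cases, pr] + archetype_shape(arch[[pr]], lt)
    }
  }

  if (config$covariate_missing_rate > 0) {
    hit <- which(stats::runif(n) < config$covariate_missing_rate)
    cohort$bmi[hit] <- NA_real_
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
    npx[mask] <- NA_real_
  }

  log_hr <- stats::setNames(numeric(p), config$proteins)
  log_hr[names(config$signal_log_hr)] <- unlist(config$signal_log_hr)
  archetype <- stats::setNames(rep(NA_integer_, p), config$proteins)
  if (length(arch)) archetype[names(arch)] <- as.integer(arch)

  mediation_truth <- NULL
  if (!is.null(med)) {
    mediation_truth <- lapply(names(med$beta1), function(m) {
      comp <- fourway_components(
        beta0 = 0, beta1 = med$beta1[[m]], sigma2 = 1,
        theta1 = med$theta1, theta2 = med$theta2, theta3 = med$theta3,
        a = 1, a_star = 0, m_star = 0
      )
      c(list(mediator = m, exposure = med$exposure,
             beta1 = med$beta1[[m]], theta1 = med$theta1,
             theta2 = med$theta2, theta3 = med$theta3, sigma2 = 1),
        comp)
    })
    names(mediation_truth) <- names(med$beta1)
  }

  truth <- list(
    log_hr = log_hr,
    archetype = archetype,
    cluster_labels = archetype[!is.na(archetype)],
    mediation = mediation_truth,
    lambda0 = lambda0,
    hazard_record = data.frame(
      participant_id = cohort$participant_id,
      lp = lp, censor_time = censor_time, event = event,
      stringsAsFactors = FALSE
    )
  )

  structure(list(cohort = cohort, proteins = npx, truth = truth),
            class = "sim_cohort")
}

#' Write a simulated cohort to delimited text plus a ground-truth JSON
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_data <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(dir, "cohort.csv")
  protein_path <- file.path(dir, "proteins.csv")
  truth_path <- file.path(dir, "ground_truth.json")
  utils::write.csv(sim$cohort, cohort_path, row.names = FALSE, na = "")
  pm <- data.frame(participant_id = rownames(sim$proteins),
                   sim$proteins, check.names = FALSE)
  utils::write.csv(pm, protein_path, row.names = FALSE, na = "")
  truth <- sim$truth
  truth$hazard_record <- NULL   # bulky; regenerate from the seed instead
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(cohort = cohort_path, proteins = protein_path,
              truth = truth_path))
}

#' Read a cohort table written by [write_simulated_data()] or supplied
#' externally with the same schema
#'
#' @param path CSV path with a `participant_id` key column.
#' @return A data.frame with factor covariates restored.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "followup_time", "event"))
  for (col in c("sex", "ethnicity", "smoking", "alcohol")) {
    if (col %in% names(df)) df[[col]] <- factor(df[[col]])
  }
  df
}

#' Read a participants x proteins NPX matrix from CSV
#'
#' Empty cells are read as missing values.
#'
#' @param path CSV path; first column `participant_id`, remaining columns
#'   one protein each.
#' @return Numeric matrix with participant ids as row names.
#' @export
read_protein_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_columns(df, "participant_id", where = "protein matrix")
  m <- as.matrix(df[, setdiff(names(df), "participant_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$participant_id
  m
}
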