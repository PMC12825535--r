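test_that("four-way components sum to the total effect and match the
           quadrature oracle over random parameter sweeps", {
  set.seed(41)
  rule <- gh_rule(60)
  for (r in 1:300) {
    b0 <- runif(1, -1, 1); b1 <- runif(1, -1, 1)
    s2 <- runif(1, 0.3, 2)
    t1 <- runif(1, -0.7, 0.7); t2 <- runif(1, -0.7, 0.7)
    t3 <- runif(1, -0.4, 0.4)
    ms <- runif(1, -1, 1)
    f <- fourway_components(b0, b1, 0, s2, t1, t2, t3,
                            a = 1, a_star = 0, m_star = ms)
    expect_lt(abs(f$cde + f$int_ref + f$int_med + f$pie - f$te), 1e-10)
    # closed-form Q against Gauss-Hermite integration of g(a, M)
    Qo <- function(a, ap) quad_Q(t1, t2, t3, b0 + b1 * ap, s2, a, rule)
    D <- Qo(0, 0)
    te_o <- (Qo(1, 1) - Qo(0, 0)) / D
    pie_o <- (Qo(0, 1) - Qo(0, 0)) / D
    expect_lt(abs(f$te - te_o) / max(abs(te_o), 1e-3), 1e-8)
    expect_lt(abs(f$pie - pie_o) / max(abs(pie_o), 1e-3), 1e-8)
  }
})

test_that("a null exposure->mediator path gives exactly zero PIE and
           mediated interaction", {
  f <- fourway_components(0.3, 0, 0, 1.2, 0.25, 0.4, 0.15,
                          a = 1, a_star = 0, m_star = 0.3)
  expect_identical(f$pie, 0)
  expect_identical(f$int_med, 0)
  expect_equal(f$te, f$cde + f$int_ref, tolerance = 1e-12)
})

test_that("without a product term the ERR-scale interaction components
           equal their conceptual (quadrature) values", {
  # On the excess-relative-risk scale a multiplicative model with theta3=0
  # still carries additive interaction; the components must match the
  # model-free integrals, not vanish.
  rule <- gh_rule(60)
  b0 <- 0.3; b1 <- 0.5; s2 <- 1; t1 <- 0.2; t2 <- 0.4
  f <- fourway_components(b0, b1, 0, s2, t1, t2, 0,
                          a = 1, a_star = 0, m_star = 0.3)
  Qo <- function(a, ap) quad_Q(t1, t2, 0, b0 + b1 * ap, s2, a, rule)
  D <- Qo(0, 0)
  intmed_o <- (Qo(1, 1) - Qo(0, 1) - Qo(1, 0) + Qo(0, 0)) / D
  expect_equal(f$int_med, intmed_o, tolerance = 1e-8)
  expect_gt(abs(f$int_med), 1e-3)
  # to first order in small effects the components do vanish
  f_small <- fourway_components(0.3, 0.05, 0, 1, 0.02, 0.04, 0,
                                a = 1, a_star = 0, m_star = 0.3)
  expect_lt(abs(f_small$int_med), 1e-4)
})

test_that("model fitting recovers generator parameters and rejects
           degenerate input", {
  set.seed(42)
  sim <- simulate_cohort(sim_config(
    n_participants = 20000, n_proteins = 2, event_rate = 0.02,
    mediation_spec = list(exposure = "bmi", beta1 = c(PROT0001 = 0.5),
                          theta1 = 0.2, theta2 = 0.4, theta3 = 0.1),
    seed = 42))
  mm <- fit_mediation_models(sim$cohort, "bmi", "PROT0001",
                             covariates = character(0),
                             matrix = sim$proteins)
  se_b1 <- summary(mm$mediator_model)$coefficients[".a", 2]
  se_t <- sqrt(diag(mm$outcome_model$var))
  names(se_t) <- names(coef(mm$outcome_model))
  expect_lt(abs(mm$beta1 - 0.5), 3 * se_b1)
  expect_lt(abs(mm$theta1 - 0.2), 3 * se_t[".a"])
  expect_lt(abs(mm$theta2 - 0.4), 3 * se_t[".m"])
  expect_lt(abs(mm$theta3 - 0.1), 3 * se_t[".a:.m"])
  expect_lt(abs(mm$sigma2 - 1), 0.05)

  # permuted exposure: both legs null
  shuf <- sim$cohort
  shuf$bmi <- sample(shuf$bmi)
  mm0 <- fit_mediation_models(shuf, "bmi", "PROT0002",
                              covariates = character(0),
                              matrix = sim$proteins)
  expect_lt(abs(mm0$beta1), 3 * summary(mm0$mediator_model)$coefficients[".a", 2])

  expect_error(
    fit_mediation_models(sim$cohort, "bmi", rep(1, 20000),
                         covariates = character(0)),
    "constant")
  expect_warning(
    fit_mediation_models(quick_surv_cohort(300, base_rate = 1.2, seed = 1),
                         "bmi", rnorm(300), covariates = character(0)),
    "event fraction")
})

test_that("decomposition of fitted models recovers a known mediation
           proportion and is invariant to mediator rescaling", {
  set.seed(43)
  sim <- simulate_cohort(sim_config(
    n_participants = 20000, n_proteins = 1, event_rate = 0.02,
    mediation_spec = list(exposure = "bmi", beta1 = c(PROT0001 = 0.5),
                          theta1 = 0.2, theta2 = 0.4, theta3 = 0),
    seed = 43))
  truth <- sim$truth$mediation$PROT0001
  mm <- fit_mediation_models(sim$cohort, "bmi", "PROT0001",
                             covariates = character(0),
                             matrix = sim$proteins)
  fw <- fourway_decompose(mm, n_boot = 200, seed = 43)
  expect_lt(abs(fw$cde + fw$int_ref + fw$int_med + fw$pie - fw$te), 1e-10)
  expect_true(truth$proportion_mediated >= fw$proportion_ci[[1]] &&
                truth$proportion_mediated <= fw$proportion_ci[[2]])
  expect_true(fw$significant)

  # affine rescaling of the mediator leaves the proportion unchanged
  m_resc <- 5.3 * sim$proteins[, "PROT0001"] - 2
  mm2 <- fit_mediation_models(sim$cohort, "bmi", m_resc,
                              covariates = character(0))
  fw2 <- fourway_decompose(mm2, ci = "none")
  expect_equal(fw2$proportion_mediated, fw$proportion_mediated,
               tolerance = 1e-6)
})

test_that("binary and continuous exposure paths agree on 0/1 data", {
  set.seed(44)
  n <- 4000
  a <- rbinom(n, 1, 0.45)
  m <- 0.5 * a + rnorm(n)
  cohort <- quick_surv_cohort(n, lp = 0.3 * a + 0.4 * m, base_rate = 0.1)
  cohort$expo <- a
  mm_bin <- suppressWarnings(
    fit_mediation_models(cohort, "expo", m, covariates = character(0),
                         exposure_kind = "binary"))
  fw_bin <- fourway_decompose(mm_bin, ci = "none")
  # the continuous path leaves 0/1 exposures on their natural scale, so
  # the design matrices coincide and components must match
  cohort$expo2 <- a
  mm_con <- suppressWarnings(
    fit_mediation_models(cohort, "expo2", m, covariates = character(0),
                         exposure_kind = "continuous"))
  fw_con <- fourway_decompose(mm_con, ci = "none")
  expect_equal(fw_bin$te, fw_con$te, tolerance = 1e-12)
  expect_equal(fw_bin$pie, fw_con$pie, tolerance = 1e-12)
})

test_that("mediator screening requires significance on both legs", {
  ea <- data.frame(protein = c("A", "B", "C"),
                   estimate = c(1, 1, 1), p = c(0.2, 1e-5, 1e-5))
  scan <- data.frame(protein = c("A", "B", "C"),
                     p = c(1e-5, 1e-5, 0.5))
  expect_equal(screen_mediators(ea, scan), "B")

  # null calibration: expected candidate count ~ 24 * alpha^2
  set.seed(45)
  hits <- 0
  n_sim <- 400
  for (s in seq_len(n_sim)) {
    p1 <- runif(24); p2 <- runif(24)
    hits <- hits + sum(p1 < 0.05 & p2 < 0.05)
  }
  expect_lt(abs(hits / n_sim - 24 * 0.05^2),
            3 * sqrt(24 * 0.05^2 / n_sim) + 0.02)
})

test_that("PCA aggregation follows Kaiser retention and the opposing-sign
           exclusion", {
  set.seed(46)
  n <- 500
  base <- rnorm(n)
  m <- cbind(A = base, B = 2 * base + 3, C = rnorm(n))
  rownames(m) <- sprintf("r%03d", 1:n)
  fw <- list(
    A = list(pie = 0.2, cde = 0.1),
    B = list(pie = 0.3, cde = 0.2),
    C = list(pie = 0.2, cde = -0.1)   # opposing signs -> excluded
  )
  agg <- pca_aggregate(m, fourway = fw)
  expect_setequal(agg$mediators, c("A", "B"))
  expect_equal(agg$retained, 1)
  expect_equal(agg$eigenvalues[1], 2, tolerance = 1e-10)
  expect_equal(abs(agg$loadings[1, 1]), abs(agg$loadings[2, 1]),
               tolerance = 1e-10)
  expect_equal(sd(agg$scores[, 1]), 1, tolerance = 1e-10)
  expect_error(pca_aggregate(m, fourway = fw[c(1, 3)]),
               "at least 2")

  # independent mediators: eigenvalues near 1, Kaiser retains 0..p
  m2 <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(rownames(m), paste0("I", 1:4)))
  agg2 <- suppressWarnings(pca_aggregate(m2, mediators = paste0("I", 1:4)))
  expect_true(all(abs(agg2$eigenvalues - 1) < 0.3))
  expect_gte(agg2$retained, 1)
  expect_lte(agg2$retained, 4)
})

test_that("PCA-score mediation matches the direct decomposition for a
           single component and recovers a planted two-protein pathway", {
  set.seed(47)
  sim <- simulate_cohort(sim_config(
    n_participants = 15000, n_proteins = 3, event_rate = 0.02,
    mediation_spec = list(exposure = "bmi",
                          beta1 = c(PROT0001 = 0.6, PROT0002 = 0.6),
                          theta1 = 0, theta2 = 0.35, theta3 = 0),
    seed = 47))
  agg <- pca_aggregate(sim$proteins,
                       mediators = c("PROT0001", "PROT0002"))
  expect_equal(agg$retained, 1)
  res <- mediate_via_pca(sim$cohort, agg$scores, "bmi",
                         covariates = character(0), n_boot = 100, seed = 47)
  expect_false(res$approximate)
  mmc <- fit_mediation_models(sim$cohort, "bmi", agg$scores[, 1],
                              covariates = character(0))
  direct <- fourway_decompose(mmc, n_boot = 100, seed = 47)
  expect_equal(res$components[[1]]$te, direct$te, tolerance = 1e-10)
  expect_equal(res$combined_proportion, direct$proportion_mediated,
               tolerance = 1e-10)
  # exposure acts only through the two proteins: high proportion mediated
  expect_gt(res$combined_proportion, 0.6)

  # exposure with no mediated path: CI on the proportion covers 0
  sim0 <- simulate_cohort(sim_config(
    n_participants = 8000, n_proteins = 2, event_rate = 0.02,
    mediation_spec = list(exposure = "bmi", beta1 = c(PROT0001 = 0),
                          theta1 = 0.4, theta2 = 0, theta3 = 0),
    seed = 48))
  mm0 <- fit_mediation_models(sim0$cohort, "bmi", "PROT0001",
                              covariates = character(0),
                              matrix = sim0$proteins)
  fw0 <- fourway_decompose(mm0, n_boot = 150, seed = 48)
  expect_true(fw0$proportion_ci[[1]] <= 0 && fw0$proportion_ci[[2]] >= 0)
})
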