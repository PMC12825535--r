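test_that("control matching is exact on sex, nearest on age, without
           replacement", {
  set.seed(31)
  cohort <- quick_surv_cohort(31)
  cohort$event <- c(1L, rep(0L, 30))
  cohort$sex <- factor(c("male", rep(c("male", "female"), 15)),
                       levels = c("female", "male"))
  cohort$age[1] <- 55
  ms <- match_controls(cohort, ratio = 10, seed = 1)
  expect_length(ms, 1)
  expect_length(ms[[1]]$control_ids, 10)
  ctrl <- cohort[match(ms[[1]]$control_ids, cohort$participant_id), ]
  expect_true(all(ctrl$sex == "male"))
  # selected ages are the 10 closest among the 15 same-sex controls
  pool <- cohort[-1, ][cohort$sex[-1] == "male", ]
  best <- sort(abs(pool$age - 55))[1:10]
  expect_equal(sort(abs(ctrl$age - 55)), best, tolerance = 1e-12)

  # determinism
  ms2 <- match_controls(cohort, ratio = 10, seed = 1)
  expect_identical(ms, ms2)
})

test_that("competing cases never reuse a control and shortfalls warn", {
  set.seed(32)
  cohort <- quick_surv_cohort(12)
  cohort$event <- c(1L, 1L, rep(0L, 10))
  cohort$sex <- factor(rep("female", 12), levels = c("female", "male"))
  cohort$age <- c(50, 50, 50 + seq(0.1, 1, 0.1))
  ms <- suppressWarnings(match_controls(cohort, ratio = 6, seed = 2))
  ids <- unlist(lapply(ms, `[[`, "control_ids"))
  expect_equal(length(ids), length(unique(ids)))   # no reuse
  expect_equal(length(ids), 10)                    # pool exhausted at 10
  expect_warning(match_controls(cohort, ratio = 6, seed = 2), "exhausted")
})

test_that("tied ages give a seeded random same-sex sample", {
  set.seed(33)
  cohort <- quick_surv_cohort(40)
  cohort$event <- c(1L, rep(0L, 39))
  cohort$sex <- factor(rep("male", 40), levels = c("female", "male"))
  cohort$age <- rep(60, 40)
  a <- match_controls(cohort, ratio = 10, seed = 5)
  b <- match_controls(cohort, ratio = 10, seed = 5)
  c_ <- match_controls(cohort, ratio = 10, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$control_ids, c_[[1]]$control_ids))
})

test_that("residualization removes covariate signal fitted on controls
           while preserving case-specific shifts", {
  set.seed(34)
  n <- 5000
  cohort <- quick_surv_cohort(n, base_rate = 0.1)
  m <- matrix(0, n, 2, dimnames = list(cohort$participant_id, c("A", "B")))
  m[, "A"] <- 2 * cohort$age + rnorm(n)
  m[, "B"] <- rnorm(n)
  shift <- 1.5
  m[cohort$event == 1, "B"] <- m[cohort$event == 1, "B"] + shift
  adj <- residualize(m, cohort)
  expect_lt(abs(cor(adj[, "A"], cohort$age)), 0.05)
  # null covariates: residuals close to centered values
  expect_lt(mean(abs(adj[, "B"] - (m[, "B"] - mean(m[cohort$event == 0,
                                                     "B"])))), 0.2)
  # case-only offset survives control-fitted adjustment
  gap <- mean(adj[cohort$event == 1, "B"]) - mean(adj[cohort$event == 0,
                                                      "B"])
  expect_lt(abs(gap - shift), 0.2)
})

test_that("residualization reports collinear columns", {
  set.seed(35)
  cohort <- quick_surv_cohort(50)
  cohort$dup <- cohort$age
  m <- matrix(rnorm(50), 50, 1,
              dimnames = list(cohort$participant_id, "A"))
  expect_error(residualize(m, cohort, covariates = c("age", "dup")),
               "collinear")
})

test_that("z-scores follow the matched-control definition", {
  vals <- matrix(c(4, 1, 2, 3, 10, 7, 9, 8), 4, 2,
                 dimnames = list(c("case", "c1", "c2", "c3"), c("A", "B")))
  ms <- structure(list(list(case_id = "case",
                            control_ids = c("c1", "c2", "c3"),
                            short = 0L)), class = "matched_sets")
  z <- zscore_cases(vals, ms)
  expect_equal(z["case", "A"], (4 - 2) / 1)
  expect_equal(z["case", "B"], (10 - 8) / 1)
  # case at the control mean -> z = 0
  vals2 <- vals; vals2["case", "A"] <- 2
  expect_equal(zscore_cases(vals2, ms)["case", "A"], 0)
  # affine invariance: same transform on case + its controls
  vals3 <- vals * 3.7 + 11
  expect_equal(zscore_cases(vals3, ms), z, tolerance = 1e-12)
  # zero control SD -> NA
  vals4 <- vals; vals4[c("c1", "c2", "c3"), "A"] <- 5
  expect_true(is.na(zscore_cases(vals4, ms)["case", "A"]))
})

test_that("z-scores of null cases against large matched pools are
           standard normal", {
  set.seed(36)
  n_case <- 150
  z <- numeric(n_case)
  for (i in seq_len(n_case)) {
    ctrl <- rnorm(200)
    z[i] <- (rnorm(1) - mean(ctrl)) / sd(ctrl)
  }
  # reference behaviour of the definition itself (simulation oracle)
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("LOESS is exact on linear and constant inputs", {
  set.seed(37)
  lt <- runif(60, 0, 15)
  z_lin <- 0.3 - 0.1 * lt
  curve <- fit_loess(lt, z_lin)
  grid <- lead_time_grid()
  inside <- grid >= min(lt) & grid <= max(lt)
  expect_lt(max(abs(curve[inside] - (0.3 - 0.1 * grid[inside]))), 1e-8)
  expect_true(all(is.na(curve[!inside])))
  z_const <- rep(0.7, 60)
  curve2 <- fit_loess(lt, z_const)
  expect_lt(max(abs(curve2[inside] - 0.7)), 1e-8)
  expect_error(fit_loess(lt[1:5], z_lin[1:5]), "at least 10")
})

test_that("LOESS recovers the early-rise archetype and error shrinks with
           sample size", {
  grid <- lead_time_grid()
  rec_err <- function(n, seed) {
    set.seed(seed)
    lt <- runif(n, 0, 15)
    z <- archetype_shape(1, lt) + rnorm(n, sd = 0.5)
    curve <- fit_loess(lt, z)
    interior <- grid >= 1 & grid <= 14 & !is.na(curve)
    max(abs(curve[interior] - archetype_shape(1, grid[interior])))
  }
  expect_lt(rec_err(120, 38), 0.25)
  e_small <- mean(vapply(1:6, function(s) rec_err(50, 100 + s), numeric(1)))
  e_large <- mean(vapply(1:6, function(s) rec_err(200, 200 + s), numeric(1)))
  expect_lt(e_large, e_small)
})

test_that("abnormality calling records crossings and sustained onset", {
  grid <- lead_time_grid()
  # flat null curve: nothing called
  res0 <- call_abnormal(rep(0, length(grid)))
  expect_equal(nrow(res0$crossings), 0)
  expect_true(is.na(res0$onset))
  # archetype 1: abnormal across the whole window, onset at the 15 y edge
  res1 <- call_abnormal(archetype_shape(1, grid))
  expect_equal(res1$onset, 15)
  expect_equal(nrow(res1$crossings), 1)
  # abnormal only between 10 and 2 years: crossings but no sustained onset
  curve <- ifelse(grid <= 10 & grid >= 2, 1, 0)
  res2 <- call_abnormal(curve)
  expect_equal(nrow(res2$crossings), 1)
  expect_equal(res2$crossings$from, 10)
  expect_equal(res2$crossings$to, 2)
  expect_true(is.na(res2$onset))
  # late-sustained rise: onset at the first grid point of the final run
  curve3 <- ifelse(grid <= 4, 1, 0)
  expect_equal(call_abnormal(curve3)$onset, 4)
})

test_that("Chebyshev distance and clustering behave as specified", {
  grid <- lead_time_grid()
  f <- archetype_shape(3, grid)
  curves <- cbind(a = f, b = f, c = f + 0.3, d = archetype_shape(2, grid))
  d <- as.matrix(dist(t(curves), method = "maximum"))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.3)             # constant offset exactly
  # metric axioms on the fixture
  expect_equal(d, t(d))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
  cl <- cluster_trajectories(curves, k = 3)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
})

test_that("well-separated archetype curves are recovered by both
           clustering routes", {
  set.seed(39)
  grid <- lead_time_grid()
  truth <- rep(1:4, each = 6)
  curves <- sapply(truth, function(a)
    archetype_shape(a, grid) + rnorm(length(grid), sd = 0.05))
  colnames(curves) <- sprintf("pr%02d", 1:24)
  hier <- cluster_trajectories(curves, k = 4)
  km <- cluster_trajectories(curves, k = 4, method = "kmeans", seed = 40)
  expect_gte(rand_index_adj(truth, hier$labels), 0.9)
  expect_gte(best_agreement(hier$labels, km$labels), 23)
  # hierarchical labels are seed-independent
  hier2 <- cluster_trajectories(curves, k = 4, seed = 999)
  expect_identical(hier$labels, hier2$labels)
  # k-means stable across seeds on separated fixtures
  for (s in 1:5) {
    km_s <- cluster_trajectories(curves, k = 4, method = "kmeans", seed = s)
    expect_gte(best_agreement(km$labels, km_s$labels), 23)
  }
})
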