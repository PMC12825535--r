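# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths.

# Gauss-Hermite nodes/weights by eigen-decomposition of the Jacobi matrix
# (Golub-Welsch), for integrals against exp(-x^2).
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2 * sqrt(pi))
}

# E[exp(theta1 a + theta2 M + theta3 a M)] with M ~ N(mu, sigma2), by
# numerical quadrature.
quad_Q <- function(theta1, theta2, theta3, mu, sigma2, a, rule = gh_rule(60)) {
  m <- sqrt(2 * sigma2) * rule$x + mu
  sum(rule$w / sqrt(pi) * exp(theta1 * a + theta2 * m + theta3 * a * m))
}

# Exhaustive brute-force kNN imputation oracle: plain loops, no shortcuts.
knn_oracle <- function(mat, k) {
  p <- ncol(mat)
  out <- mat
  cmeans <- sapply(seq_len(p), function(j) mean(mat[, j], na.rm = TRUE))
  for (j in seq_len(p)) {
    for (i in seq_len(nrow(mat))) {
      if (!is.na(mat[i, j])) next
      dists <- rep(Inf, p)
      for (q in seq_len(p)) {
        if (q == j) next
        both <- which(!is.na(mat[, j]) & !is.na(mat[, q]))
        if (length(both)) {
          dists[q] <- sqrt(mean((mat[both, j] - mat[both, q])^2))
        }
      }
      nbrs <- order(dists)[seq_len(min(k, sum(is.finite(dists))))]
      nbrs <- nbrs[is.finite(dists[nbrs])]
      vals <- mat[i, nbrs]
      vals <- vals[!is.na(vals)]
      out[i, j] <- if (length(vals)) mean(vals) else cmeans[j]
    }
  }
  out
}

# Small synthetic cohort shortcut for model-level tests that need a
# survival outcome but not the full generator.
quick_surv_cohort <- function(n, lp = rep(0, n), base_rate = 0.05,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cens <- runif(n, 10, 13)
  tt <- rexp(n, 1) / (base_rate / 12 * exp(lp))
  data.frame(
    participant_id = sprintf("Q%05d", seq_len(n)),
    age = runif(n, 40, 70),
    sex = factor(sample(c("female", "male"), n, TRUE)),
    ethnicity = factor(sample(c("white", "other"), n, TRUE, c(.94, .06))),
    deprivation_index = rnorm(n, 0, 3),
    smoking = factor(sample(c("never", "ever"), n, TRUE)),
    alcohol = factor(sample(c("never", "moderate", "frequent"), n, TRUE)),
    bmi = rnorm(n, 27, 4.5),
    hypertension = rbinom(n, 1, 0.27),
    diabetes = rbinom(n, 1, 0.05),
    followup_time = pmin(tt, cens),
    event = as.integer(tt <= cens),
    lead_time = ifelse(tt <= cens, pmin(tt, cens), NA_real_)
  )
}

# Adjusted Rand index between two labelings (contingency-table closed
# form), independent of any clustering package.
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Best cluster-agreement count between two labelings over all label
# permutations (k small).
best_agreement <- function(a, b) {
  k <- max(b)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  max(vapply(perms(seq_len(k)),
             function(p) sum(p[b] == a), numeric(1)))
}
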