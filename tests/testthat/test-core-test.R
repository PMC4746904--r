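test_that("Q matches direct quadratic-form arithmetic on a small instance", {
  y <- c(1, 2, 3, 4)
  X <- cbind(c(1, 0, 1, 0), c(0, 1, 1, 1))
  nm <- fit_null(y)
  expect_equal(q_statistic(nm, covariate_set(X)), oracle_q(y, X))
  # and with a confounder in the null design
  y5 <- c(2, 1, 4, 3, 6)
  c1 <- c(1, 0, 2, 1, 3)
  X5 <- matrix(c(1, -1, 0, 2, 1, 0, 1, 1, -2, 0), 5, 2)
  nm5 <- fit_null(y5, confounders = cbind(c1))
  expect_equal(q_statistic(nm5, covariate_set(X5)),
               oracle_q(y5, X5, confounders = cbind(c1)))
})

test_that("Q is zero for all-zero covariates and location-invariant in y", {
  nm <- fit_null(c(1, 2, 3, 4))
  expect_equal(q_statistic(nm, covariate_set(matrix(0, 4, 3))), 0)
  set.seed(7)
  y <- rnorm(10); X <- matrix(rnorm(30), 10, 3)
  cs <- covariate_set(X)
  q1 <- q_statistic(fit_null(y), cs)
  q2 <- q_statistic(fit_null(y + 17.5), cs)
  expect_equal(q1, q2)
})

test_that("Q scales quadratically in X while T is scale-invariant", {
  y <- c(1, 2, 3, 4)
  X <- cbind(c(1, 0, 1, 0), c(0, 1, 1, 1))
  nm <- fit_null(y)
  cs1 <- covariate_set(X); cs3 <- covariate_set(3 * X)
  expect_equal(q_statistic(nm, cs3), 9 * q_statistic(nm, cs1))
  m1 <- moments_q(nm, cs1); m3 <- moments_q(nm, cs3)
  t1 <- standardized_t(q_statistic(nm, cs1), m1$expected_q, m1$var_q)
  t3 <- standardized_t(q_statistic(nm, cs3), m3$expected_q, m3$var_q)
  expect_equal(t1, t3)
})

test_that("moments: unit vector orthogonal to the intercept gives E[Q] = 1/d", {
  x <- c(1, -1, 0, 0) / sqrt(2)   # unit norm, sums to zero
  nm <- fit_null(c(2, 1, 4, 3))
  m <- moments_q(nm, covariate_set(cbind(x)))
  expect_equal(m$expected_q, 1 / 3)
  expect_equal(m$trace_term, 1)
})

test_that("moments agree with a spherical Monte-Carlo oracle", {
  set.seed(11)
  y <- rnorm(10)
  X <- matrix(rnorm(50), 10, 5)
  nm <- fit_null(y)
  m <- moments_q(nm, covariate_set(X))
  qs <- oracle_spherical_q(X, n_draws = 50000, seed = 101)
  se_mean <- sd(qs) / sqrt(length(qs))
  se_var <- sd((qs - mean(qs))^2) / sqrt(length(qs))
  expect_lt(abs(m$expected_q - mean(qs)), 3 * se_mean)
  expect_lt(abs(m$var_q - var(qs)), 3 * se_var)
})

test_that("mean of Q over all 24 permutations equals the spherical mean", {
  y <- c(0.4, -1.1, 2.0, 0.3)
  X <- matrix(c(1.2, 0.1, -0.5, 0.7, 0.0, -1.0, 0.4, 0.9), 4, 2)
  nm <- fit_null(y)
  qs <- vapply(oracle_perms(4L), function(p) oracle_q(y[p], X), numeric(1L))
  m <- moments_q(nm, covariate_set(X))
  # with an intercept-only null, exchangeability makes the permutation mean
  # of Q equal tr(A)/d exactly
  expect_equal(mean(qs), m$expected_q, tolerance = 1e-12)
})

test_that("degenerate sets: constant-on-residual-space covariates are flagged", {
  nm <- fit_null(c(1, 2, 3, 5))
  cs <- covariate_set(matrix(1, 4, 2))   # intercept column: zero after projection
  expect_warning(m <- moments_q(nm, cs), "constant")
  expect_true(is.na(m$var_q))
  expect_error(standardized_t(1, 1, 0), "positive")
  res <- joint_statistic(nm, cs)
  expect_true(any(grepl("constant_on_residual_space", res$flags)))
})

test_that("standardized_t is plain centering and scaling", {
  expect_equal(standardized_t(2, 1, 4), 0.5)
  expect_equal(standardized_t(3, 3, 2), 0)
})

test_that("joint statistic reduces to Q for a single set and stores components", {
  set.seed(3)
  y <- rnorm(12)
  nm <- fit_null(y)
  cs <- covariate_set(matrix(rnorm(48), 12, 4), name = "CN")
  res <- joint_statistic(nm, cs)
  expect_equal(res$combined, q_statistic(nm, cs))
  expect_equal(res$combine_mode, "sum")
  expect_equal(unname(res$set_sizes), 4L)
})

test_that("merged-set identity: sum mode equals Q on column-bound covariates", {
  for (seed in 1:10) {
    for (M in 2:3) {
      inst <- random_instance(n = sample(5:50, 1), js = sample(1:8, M), seed = seed * 100 + M)
      res <- joint_statistic(inst$null, inst$sets, mode = "sum")
      merged <- covariate_set(do.call(cbind, lapply(inst$sets, `[[`, "values")))
      q_merged <- q_statistic(inst$null, merged)
      expect_equal(res$combined, q_merged, tolerance = 1e-10)
    }
  }
})

test_that("centered-squared mode matches per-set computation on three sets", {
  set.seed(21)
  y <- rnorm(6)
  nm <- fit_null(y)
  sets <- lapply(1:3, function(m)
    covariate_set(matrix(rnorm(12), 6, 2), name = paste0("s", m)))
  res <- joint_statistic(nm, sets, mode = "centered_squared")
  P <- oracle_projection(6)
  manual <- sum(vapply(sets, function(s) {
    A <- P %*% s$values %*% t(s$values) %*% P
    (oracle_q(y, s$values) - sum(diag(A)) / nm$df_resid)^2
  }, numeric(1L)))
  expect_equal(res$combined, manual)
})

test_that("weights multiply per-set contributions", {
  set.seed(5)
  y <- rnorm(8)
  nm <- fit_null(y)
  s1 <- covariate_set(matrix(rnorm(16), 8, 2), name = "a")
  s2 <- covariate_set(matrix(rnorm(24), 8, 3), name = "b")
  res <- joint_statistic(nm, list(s1, s2), weights = c(2, 0.5))
  expect_equal(res$combined,
               2 * q_statistic(nm, s1) + 0.5 * q_statistic(nm, s2))
})

test_that("all-zero sets contribute nothing to sum mode and are flagged", {
  set.seed(9)
  nm <- fit_null(rnorm(6))
  s1 <- covariate_set(matrix(rnorm(12), 6, 2), name = "real")
  s0 <- covariate_set(matrix(0, 6, 4), name = "ME")
  res <- suppressWarnings(joint_statistic(nm, list(s1, s0)))
  expect_equal(res$combined, q_statistic(nm, s1))
  expect_true(any(grepl("zero_set:ME", res$flags)))
})

test_that("column standardization makes T invariant to per-probe rescaling", {
  set.seed(13)
  y <- rnorm(15)
  nm <- fit_null(y)
  X <- matrix(rnorm(60), 15, 4)
  scaled <- sweep(X, 2L, c(10, 0.1, 3, 1), "*")
  r1 <- joint_statistic(nm, covariate_set(X), standardize = TRUE)
  r2 <- joint_statistic(nm, covariate_set(scaled), standardize = TRUE)
  expect_equal(r1$combined, r2$combined)
})
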