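test_that("tie saturation: permutation-invariant statistics give p = 1", {
  nm <- fit_null(c(1, 3, 2, 5, 4, 6))
  cs <- covariate_set(matrix(5, 6, 2))   # constant columns: X^t r = 0 always
  p <- suppressWarnings(
    permutation_pvalue(nm, cs, plan = permutation_plan(999, seed = 1)))
  expect_equal(as.numeric(p), 1)
})

test_that("add-one estimator bounds the smallest attainable p-value", {
  set.seed(2)
  n <- 30
  x <- rnorm(n)
  y <- 5 * x + rnorm(n, 0, 0.01)         # overwhelming association
  nm <- fit_null(y)
  p <- permutation_pvalue(nm, covariate_set(cbind(x)),
                          plan = permutation_plan(999, seed = 3))
  expect_equal(as.numeric(p), 1 / 1000)
  expect_false(attr(p, "exhaustive"))
})

test_that("exhaustive enumeration reproduces the exact p-value at N = 5", {
  y <- c(1.2, -0.7, 0.3, 2.1, -1.5)
  X <- matrix(c(0.5, 1.0, -0.3, 1.7, -0.9,
                -1.1, 0.2, 0.8, 0.1, 0.6), 5, 2)
  nm <- fit_null(y)
  p <- permutation_pvalue(nm, covariate_set(X),
                          plan = permutation_plan(999, seed = 8))
  expect_true(attr(p, "exhaustive"))
  # independent brute-force loop over all 120 permutations of the response
  q_obs <- oracle_q(y, X)
  qs <- vapply(oracle_perms(5L), function(pm) oracle_q(y[pm], X), numeric(1L))
  expect_equal(as.numeric(p), mean(qs >= q_obs - 1e-12))
  expect_equal(attr(p, "n_perm"), 120L)
})

test_that("per-set p-values come from the same stream as the joint one", {
  set.seed(4)
  y <- rnorm(20)
  nm <- fit_null(y)
  s1 <- covariate_set(matrix(rnorm(60), 20, 3), name = "CN")
  s2 <- covariate_set(matrix(rnorm(40), 20, 2), name = "ME")
  p <- permutation_pvalue(nm, list(s1, s2),
                          plan = permutation_plan(499, seed = 9))
  pps <- attr(p, "p_per_set")
  expect_named(pps, c("CN", "ME"))
  p1 <- permutation_pvalue(nm, s1, plan = permutation_plan(499, seed = 9))
  expect_equal(unname(pps["CN"]), as.numeric(p1))
})

test_that("identical seeds give identical p-values", {
  set.seed(6)
  y <- rnorm(25)
  nm <- fit_null(y)
  cs <- covariate_set(matrix(rnorm(100), 25, 4))
  p1 <- permutation_pvalue(nm, cs, plan = permutation_plan(199, seed = 5))
  p2 <- permutation_pvalue(nm, cs, plan = permutation_plan(199, seed = 5))
  expect_identical(as.numeric(p1), as.numeric(p2))
})

test_that("spectral null: rank-1 case and eigenvalue identities", {
  x <- c(2, -2, 1, -1, 0, 0)             # orthogonal to the intercept
  nm <- fit_null(c(1, 4, 2, 6, 3, 5))
  spec <- spectral_null(nm, covariate_set(cbind(x)))
  expect_equal(spec$rank, 1L)
  expect_equal(spec$eigenvalues, sum(x^2))
  # J-space eigenvalues match the dense N-space decomposition, and their
  # sum equals the trace of the projected X X^t, on random 8 x 3 instances
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(24), 8, 3)
    nm8 <- fit_null(rnorm(8))
    spec8 <- spectral_null(nm8, covariate_set(X))
    P <- oracle_projection(8)
    A <- P %*% X %*% t(X) %*% P
    evA <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(spec8$eigenvalues, evA[evA > 1e-10 * max(evA)],
                 tolerance = 1e-8)
    expect_equal(sum(spec8$eigenvalues), sum(diag(A)))
  }
})

test_that("spectral null rejects covariates with no residual-space variance", {
  nm <- fit_null(c(1, 2, 3, 4))
  expect_error(spectral_null(nm, covariate_set(matrix(1, 4, 2))), "variance")
})

test_that("asymptotic p-value is monotone in the observed statistic", {
  set.seed(10)
  nm <- fit_null(rnorm(12))
  cs <- covariate_set(matrix(rnorm(48), 12, 4))
  spec <- spectral_null(nm, cs)
  qs <- seq(0.01, max(spec$eigenvalues) * 0.99, length.out = 25)
  ps <- vapply(qs, asymptotic_pvalue, numeric(1L), spec = spec)
  expect_true(all(diff(ps) <= 1e-9))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_equal(asymptotic_pvalue(max(spec$eigenvalues) * 1.01, spec), 0)
  expect_equal(asymptotic_pvalue(0, spec), 1)
})

test_that("single-covariate tail matches the Beta(1/2, (N-2)/2) law", {
  set.seed(12)
  n <- 10
  x <- rnorm(n)
  nm <- fit_null(rnorm(n))
  spec <- spectral_null(nm, covariate_set(cbind(x)))
  lam <- spec$eigenvalues
  for (frac in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
    q <- frac * lam
    p_beta <- pbeta(frac, 1 / 2, (n - 2) / 2, lower.tail = FALSE)
    expect_lt(abs(asymptotic_pvalue(q, spec) - p_beta), 1e-4)
  }
})

test_that("permutation and asymptotic p-values agree on gaussian data", {
  for (seed in 1:5) {
    set.seed(seed + 40)
    n <- 50
    y <- rnorm(n)
    cs <- covariate_set(matrix(rnorm(n * 5), n, 5))
    nm <- fit_null(y)
    p_perm <- as.numeric(
      permutation_pvalue(nm, cs, plan = permutation_plan(5000, seed = seed)))
    p_asym <- asymptotic_pvalue(q_statistic(nm, cs), spectral_null(nm, cs))
    se <- sqrt(p_asym * (1 - p_asym) / 5000)
    expect_lt(abs(p_perm - p_asym), 3 * se + 1 / 5001)
  }
})

test_that("asymptotic p-values are uniform under the gaussian null", {
  set.seed(77)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6)
  Z <- matrix(rnorm(n * 4), n, 4)
  ps <- replicate(400, {
    nm <- fit_null(rnorm(n))
    asymptotic_pvalue(
      joint_statistic(nm, list(covariate_set(X, "a"), covariate_set(Z, "b")))$combined,
      spectral_null(nm, list(covariate_set(X, "a"), covariate_set(Z, "b"))))
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
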