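test_that("implied correlation reproduces the design values", {
  expect_equal(round(implied_correlation(2.25, 1, +1), 2), 0.83)
  expect_equal(round(implied_correlation(2.25, 5, +1), 2), 0.56)
  expect_equal(round(implied_correlation(2.25, 1, -1), 2), -0.83)
  expect_equal(implied_correlation(3.7, 3.7, +1), sqrt(0.5))
  expect_error(implied_correlation(-1, 1), "positive")
  expect_error(implied_correlation(1, 1, 2), "link_sign")
})

test_that("linked sets realize the implied correlation structure", {
  sim <- simulate_linked_sets(n_samples = 100000, n_probes = 3,
                              var_w = 1, seed = 99)
  for (k in 1:3)
    expect_lt(abs(cor(sim$X[k, ], sim$Z[k, ]) - implied_correlation(2.25, 1)),
              0.01)
  # cross-pair correlation is zero by construction
  expect_lt(abs(cor(sim$X[1, ], sim$Z[2, ])), 3 / sqrt(100000))
  # Var(Z) = Var(X) + Var(W)
  expect_equal(var(sim$Z[1, ]), 2.25 + 1, tolerance = 0.05)
  expect_equal(mean(sim$X), 1, tolerance = 0.02)
  # negative linkage flips the sign
  simneg <- simulate_linked_sets(1000, 2, var_w = 1, link_sign = -1, seed = 3)
  expect_lt(cor(simneg$X[1, ], simneg$Z[1, ]), -0.7)
})

test_that("identical seeds give bit-identical simulations", {
  a <- simulate_linked_sets(50, 10, seed = 7)
  b <- simulate_linked_sets(50, 10, seed = 7)
  expect_identical(a$X, b$X)
  expect_identical(a$Z, b$Z)
  sa <- simulate_region(a$X, a$Z, "additive", seed = 5)
  sb <- simulate_region(b$X, b$Z, "additive", seed = 5)
  expect_identical(sa$Y, sb$Y)
})

test_that("covariance-driven simulation honours the target covariance", {
  cov <- diag(4)
  cov[1, 3] <- cov[3, 1] <- 0.5
  sim <- simulate_from_covariance(cov, n_x = 2, n_samples = 100000, seed = 17)
  expect_equal(dim(sim$X), c(2L, 100000L))
  expect_equal(cor(sim$X[1, ], sim$Z[1, ]), 0.5, tolerance = 0.02)
  expect_lt(abs(cor(sim$X[2, ], sim$Z[2, ])), 3 / sqrt(100000))
  bad <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3, -1
  expect_error(simulate_from_covariance(bad, 1, 10), "semi-definite")
})

test_that("eigen- and Cholesky-based draws agree in distribution", {
  cov <- matrix(0.4, 3, 3); diag(cov) <- 1
  sim <- simulate_from_covariance(cov, n_x = 1, n_samples = 10000, seed = 23)
  set.seed(24)
  chol_draws <- t(chol(cov)) %*% matrix(rnorm(3 * 10000), 3)
  for (k in 1:3) {
    ks <- suppressWarnings(
      ks.test(rbind(sim$X, sim$Z)[k, ], chol_draws[k, ]))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("region types are produced with correct labels and truth", {
  sim <- simulate_linked_sets(30, 40, seed = 1)
  for (rt in c("x_only", "additive", "multiplicative", "complementary")) {
    st <- simulate_region(sim$X, sim$Z, rt, n_associated = 15, seed = 2)
    expect_s3_class(st, "simulated_study")
    expect_equal(st$config$region_type, rt)
    expect_equal(sum(st$truth), 15L)
    expect_true(all(which(st$truth) == 1:15))
    expect_equal(dim(st$Y), dim(sim$X))
  }
  expect_error(simulate_region(sim$X, sim$Z, "x_only", n_associated = 100),
               "exceeds")
})

test_that("x_only regions correlate associated responses with X, not noise", {
  sim <- simulate_linked_sets(200, 60, var_w = 1, seed = 41)
  st <- simulate_region(sim$X, sim$Z, "x_only", n_associated = 30, seed = 42)
  cors <- vapply(seq_len(60), function(i) abs(cor(st$Y[i, ], sim$X[i, ])),
                 numeric(1L))
  tt <- t.test(cors[st$truth], cors[!st$truth], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("zero effect size collapses all regions to pure noise", {
  sim <- simulate_linked_sets(100, 20, seed = 51)
  st <- simulate_region(sim$X, sim$Z, "additive", effect_size = 0, seed = 52)
  cors <- vapply(seq_len(20), function(i) cor(st$Y[i, ], sim$X[i, ]),
                 numeric(1L))
  expect_true(all(abs(cors) < 4 / sqrt(100)))
})

test_that("complementary regions drive each sample half by one set", {
  sim <- simulate_linked_sets(400, 10, var_w = 100, seed = 61)  # X, Z near-independent
  st <- simulate_region(sim$X, sim$Z, "complementary", n_associated = 10,
                        effect_size = 2, noise_sd = 0.5, seed = 62)
  half <- 1:200
  cx_first <- abs(cor(st$Y[1, half], sim$X[1, half]))
  cz_first <- abs(cor(st$Y[1, half], sim$Z[1, half]))
  cz_second <- abs(cor(st$Y[1, -half], sim$Z[1, -half]))
  expect_gt(cx_first, cz_first)
  expect_gt(cz_second, 0.3)
})

test_that("a study round-trips through the TSV writer", {
  tmp <- withr::local_tempdir()
  sim <- simulate_linked_sets(10, 5, seed = 71)
  st <- simulate_region(sim$X, sim$Z, "x_only", seed = 72)
  paths <- write_study(st, file.path(tmp, "sim_"))
  expect_identical(read_matrix(paths[["Y"]]), st$Y)
  truth <- read.delim(paths[["truth"]])
  expect_equal(truth$truth, st$truth)
  cfg <- read_run_config(paths[["config"]])
  expect_equal(cfg$region_type, "x_only")
})
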