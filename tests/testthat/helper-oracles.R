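# Independent oracles used across the suite.  These deliberately take the
# slow, explicit route (dense N x N matrices, double loops, enumeration)
# so they share no code path with the package internals they check.

# Q via element-wise evaluation of the defining quadratic form.
oracle_q <- function(y, X, confounders = NULL) {
  D <- cbind(rep(1, length(y)), confounders)
  b <- solve(t(D) %*% D, t(D) %*% y)          # normal equations
  r <- y - D %*% b
  num <- as.numeric(t(r) %*% X %*% t(X) %*% r)
  num / as.numeric(t(r) %*% r)
}

# Dense projection matrix onto the residual space of an intercept(-plus-
# confounder) design.
oracle_projection <- function(n, confounders = NULL) {
  D <- cbind(rep(1, n), confounders)
  diag(n) - D %*% solve(t(D) %*% D) %*% t(D)
}

# All permutations of 1..n by brute force: every n-tuple over 1..n is
# generated and non-permutations are discarded (fine for n <= 5).
oracle_perms <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  keep <- apply(grid, 1L, function(row) length(unique(row)) == n)
  lapply(seq_len(sum(keep)), function(i) unname(grid[keep, ][i, ]))
}

# Spherical Monte-Carlo draws of Q: residual direction uniform on the unit
# sphere of the residual space.
oracle_spherical_q <- function(X, n_draws, seed, confounders = NULL) {
  set.seed(seed)
  n <- nrow(X)
  P <- oracle_projection(n, confounders)
  G <- matrix(rnorm(n * n_draws), n, n_draws)
  U <- P %*% G
  U <- sweep(U, 2L, sqrt(colSums(U^2)), "/")
  colSums((t(X) %*% U)^2)
}

# AUC by exhaustive pairwise Mann-Whitney counting with ties at 1/2.
oracle_auc <- function(p, truth) {
  pos <- p[truth]; neg <- p[!truth]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Random test instance: response + M covariate sets.
random_instance <- function(n, js, seed) {
  set.seed(seed)
  y <- rnorm(n)
  sets <- lapply(seq_along(js), function(m)
    covariate_set(matrix(rnorm(n * js[m]), n, js[m]),
                  name = paste0("set", m)))
  list(y = y, null = fit_null(y), sets = sets)
}
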