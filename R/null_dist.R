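#' Describe a permutation scheme
#'
#' P-values are computed by default against the permutation null: the
#' residual vector is permuted across samples and the statistic recomputed.
#' Without confounders this is identical to permuting the response itself
#' (the intercept fit is permutation-invariant); with confounders,
#' permuting the null-model residuals is the standard approximate scheme.
#' When `N! <= n_perm` and there are no confounders the full permutation
#' group is enumerated instead of sampled, giving exact p-values.
#'
#' @param n_perm Number of random permutations (`>= 99`).
#' @param seed Integer seed; one permutation stream is generated per plan
#'   and can be reused across many responses, which both saves time and
#'   makes p-values comparable across responses.
#' @param scheme `"permute_residuals"` (default) or `"permute_response"`;
#'   they coincide when the null design is the intercept alone.
#' @return An object of class `permutation_plan`.
#' @export
permutation_plan <- function(n_perm = 999L, seed = 42L,
                             scheme = c("permute_residuals", "permute_response")) {
  scheme <- match.arg(scheme)
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  structure(list(n_perm = n_perm, seed = as.integer(seed), scheme = scheme),
            class = "permutation_plan")
}

# All N! permutations of 1..n, one per column (n <= 8 or so).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(k, rest[sub[, j]])
    }
  }
  out
}

# Permutation index matrix (N x B).  Exhaustive enumeration excludes the
# identity column from the random stream semantics: for exhaustive plans the
# p-value is the exact fraction over the whole group (identity included).
permutation_indices <- function(n, plan, exhaustive_ok = TRUE) {
  n_total <- factorial(n)
  if (exhaustive_ok && n_total <= plan$n_perm) {
    return(structure(all_permutations(n), exhaustive = TRUE))
  }
  old <- local_seed(plan$seed)
  on.exit(restore_seed(old), add = TRUE)
  idx <- replicate(plan$n_perm, sample.int(n))
  structure(idx, exhaustive = FALSE)
}

# Per-set Q statistics along a permutation stream.  Returns observed per-set
# Q (vector) and a B x M matrix of permuted per-set Qs.  The residual norm is
# permutation-invariant, so the denominator is computed once.
perm_q_streams <- function(null, sets, idx) {
  r <- null$residuals
  rp <- matrix(r[idx], nrow = null$n)   # N x B permuted residuals
  obs <- numeric(length(sets))
  qs <- matrix(0, ncol(idx), length(sets))
  for (m in seq_along(sets)) {
    xt <- t(sets[[m]]$values)           # J x N
    obs[m] <- sum((xt %*% r)^2) / null$rss
    qs[, m] <- colSums((xt %*% rp)^2) / null$rss
  }
  list(obs = obs, perm = qs)
}

combine_q <- function(qmat, mode, w, expected_q, var_q) {
  switch(mode,
    sum = as.vector(qmat %*% w),
    centered_squared = as.vector(sweep(qmat, 2L, expected_q, "-")^2 %*% w),
    standardized_sum = {
      keep <- is.finite(var_q) & var_q > 0
      z <- sweep(sweep(qmat[, keep, drop = FALSE], 2L, expected_q[keep], "-"),
                 2L, sqrt(var_q[keep]), "/")
      as.vector(z %*% w[keep])
    })
}

#' Permutation p-value for the joint statistic
#'
#' Computes the observed joint statistic and compares it with its value on
#' permuted residuals.  For sampled permutations the add-one estimator
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)` is used, so `p` lies in
#' `(0, 1]` and the smallest attainable value is `1/(n_perm + 1)`; ties
#' count against rejection.  For exhaustive plans `p` is the exact fraction
#' of the full permutation group (identity included) at or above the
#' observed value.
#'
#' @inheritParams joint_statistic
#' @param plan A [permutation_plan()].
#' @param idx Optional precomputed permutation index matrix (`N x B`), as
#'   used internally by [run_genomewide()] to share one stream across
#'   responses; overrides `plan`'s stream (but not its estimator).
#' @return Joint p-value in `(0, 1]`, with attributes `p_per_set` (per-set
#'   permutation p-values from the same stream) and `n_perm`.
#' @export
permutation_pvalue <- function(null, sets,
                               mode = c("sum", "centered_squared", "standardized_sum"),
                               weights = NULL, plan = permutation_plan(),
                               standardize = FALSE, idx = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(null, "mgt_null"), inherits(plan, "permutation_plan"))
  sets <- as_covariate_sets(sets)
  if (!is.null(weights)) {
    for (m in seq_along(sets)) sets[[m]]$weight <- weights[m]
  }
  if (standardize) {
    for (m in seq_along(sets))
      sets[[m]]$values <- standardize_columns(sets[[m]]$values)
  }
  for (s in sets) check_alignment(null, s)
  if (is.null(idx)) {
    exhaustive_ok <- plan$scheme == "permute_residuals" || !null$has_confounders
    idx <- permutation_indices(null$n, plan, exhaustive_ok = exhaustive_ok)
  }
  exhaustive <- isTRUE(attr(idx, "exhaustive"))
  w <- vapply(sets, `[[`, numeric(1L), "weight")
  streams <- perm_q_streams(null, sets, idx)
  eq <- vq <- numeric(length(sets))
  if (mode != "sum") {
    for (m in seq_along(sets)) {
      mom <- suppressWarnings(moments_q(null, sets[[m]]))
      eq[m] <- mom$expected_q; vq[m] <- mom$var_q
    }
  }
  obs <- combine_q(matrix(streams$obs, 1L), mode, w, eq, vq)
  stat <- combine_q(streams$perm, mode, w, eq, vq)
  tol <- 1e-12 * max(1, abs(obs))
  pfun <- function(perm, o) {
    hits <- sum(perm >= o - tol)
    if (exhaustive) hits / length(perm) else (1 + hits) / (1 + length(perm))
  }
  p <- pfun(stat, obs)
  p_set <- vapply(seq_along(sets),
                  function(m) pfun(streams$perm[, m], streams$obs[m]),
                  numeric(1L))
  structure(p, p_per_set = stats::setNames(p_set, names(sets)),
            n_perm = ncol(idx), exhaustive = exhaustive)
}

#' Spectrum of the joint statistic's null distribution
#'
#' Under the gaussian linear model, `Q` for the (merged, weighted) covariate
#' matrix is a ratio of quadratic forms in the residual direction, and its
#' exact finite-sample null law is determined by the eigenvalues of the
#' covariate Gram matrix projected onto the residual space.  Only the `sum`
#' combination mode has this single-matrix representation.  Eigenvalues are
#' obtained from the projected `J x J` cross-product (never the `N x N`
#' form); values below `tolerance` times the largest are treated as zero.
#'
#' @inheritParams joint_statistic
#' @param tolerance Relative zero threshold for eigenvalues.
#' @return Object of class `spectral_null`: `eigenvalues` (descending,
#'   positive part), `df_resid`, `rank`.
#' @export
spectral_null <- function(null, sets, weights = NULL, standardize = FALSE,
                          tolerance = 1e-10) {
  stopifnot(inherits(null, "mgt_null"))
  sets <- as_covariate_sets(sets)
  if (!is.null(weights)) {
    for (m in seq_along(sets)) sets[[m]]$weight <- weights[m]
  }
  if (standardize) {
    for (m in seq_along(sets))
      sets[[m]]$values <- standardize_columns(sets[[m]]$values)
  }
  for (s in sets) check_alignment(null, s)
  merged <- do.call(cbind, lapply(sets, function(s) sqrt(s$weight) * s$values))
  xp <- project_residual_space(null, merged)
  g <- crossprod(xp)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > tolerance * max(ev, 0)]
  if (!length(ev))
    stop("covariates have no variance on the residual space")
  structure(list(eigenvalues = sort(ev, decreasing = TRUE),
                 df_resid = null$df_resid, rank = length(ev),
                 tolerance = tolerance),
            class = "spectral_null")
}

# Imhof-type characteristic-function inversion for P(sum w_i chi2_1,i >= 0),
# each chi-square with one degree of freedom.
imhof_positive_tail <- function(w, abs_tol = 1e-6) {
  w <- w[w != 0]
  if (!length(w)) return(NA_real_)
  if (all(w > 0)) return(1)
  if (all(w < 0)) return(0)
  integrand <- function(u) {
    out <- numeric(length(u))
    for (i in seq_along(u)) {
      ui <- u[i]
      if (ui == 0) { out[i] <- sum(w) / 2; next }
      theta <- 0.5 * sum(atan(w * ui))
      log_rho <- 0.25 * sum(log1p((w * ui)^2))
      out[i] <- sin(theta) / (ui * exp(log_rho))
    }
    out
  }
  val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                          abs.tol = abs_tol * pi, subdivisions = 2000L,
                          stop.on.error = FALSE)
  p <- 0.5 + val$value / pi
  min(max(p, 0), 1)
}

#' Tail probability of the ratio-of-quadratic-forms null
#'
#' Evaluates `P(Q >= q_obs)` where the null law of `Q` is
#' \deqn{Q \;=\; \frac{\sum_i \lambda_i \chi^2_{1,i}}{\sum_{j=1}^{d} \chi^2_{1,j}},}
#' a ratio of weighted sums of one-degree-of-freedom chi-squares over the
#' `d`-dimensional residual space (zero eigenvalues padded up to `d`).  The
#' event `Q >= q` is rewritten as `sum_i (lambda_i - q) chi2_1,i >= 0` and
#' evaluated by numerical inversion of the characteristic function
#' (Imhof-type adaptive quadrature, absolute accuracy about 1e-6).
#'
#' @param q_obs Observed statistic (finite).
#' @param spec A [spectral_null()] object.
#' @return p-value in `[0, 1]`, nonincreasing in `q_obs`.
#' @export
asymptotic_pvalue <- function(q_obs, spec) {
  stopifnot(inherits(spec, "spectral_null"), is.finite(q_obs))
  lam <- spec$eigenvalues
  d <- spec$df_resid
  if (q_obs > max(lam)) return(0)
  lower_support <- if (spec$rank < d) 0 else min(lam)
  if (q_obs <= lower_support) return(1)
  w <- c(lam, rep(0, max(0L, d - spec$rank))) - q_obs
  imhof_positive_tail(w)
}
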