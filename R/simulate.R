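#' Correlation implied by the additive linkage Z = s·X + W
#'
#' When each `Z` probe is built from its matched `X` probe as
#' `Z = s\,X + W` with independent noise `W`, the matched-pair correlation
#' is \deqn{Cor(X, Z) = s\,\sqrt{Var(X) / (Var(X) + Var(W))},}
#' while unmatched pairs are uncorrelated.  With `Var(X) = 2.25` this gives
#' 0.83 for `Var(W) = 1` and 0.56 for `Var(W) = 5`.
#'
#' @param var_x,var_w Positive variances of `X` and of the linkage noise.
#' @param link_sign `+1` or `-1`, the sign `s` of the linkage.
#' @return Correlation in `[-1, 1]`.
#' @export
implied_correlation <- function(var_x, var_w, link_sign = 1) {
  if (!is.numeric(var_x) || var_x <= 0 || !is.numeric(var_w) || var_w <= 0)
    stop("variances must be positive")
  if (!link_sign %in% c(-1, 1)) stop("link_sign must be +1 or -1")
  link_sign * sqrt(var_x / (var_x + var_w))
}

#' Simulate a pair of linked covariate sets
#'
#' Generates `X` with iid `N(mean_x, var_x)` entries and
#' `Z = link_sign * X + W` with `W` iid `N(0, var_w)`, so matched probe
#' pairs have correlation [implied_correlation()] and unmatched pairs are
#' independent.  The default `mean_x = 1`, `var_x = 2.25` mimics
#' copy-number-like covariates centered near the diploid value with
#' moderate spread.
#'
#' @param n_samples,n_probes Dimensions (`I = J = K` matched probes).
#' @param mean_x,var_x Marginal mean and variance of `X` entries.
#' @param var_w Linkage-noise variance; smaller values mean stronger
#'   X-Z correlation.
#' @param link_sign `+1` (default) or `-1`.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with matrices `X` and `Z` (probes in rows, samples in
#'   columns) and the config used.
#' @export
simulate_linked_sets <- function(n_samples, n_probes, mean_x = 1,
                                 var_x = 2.25, var_w = 1, link_sign = 1,
                                 seed = 42L) {
  stopifnot(n_samples >= 2, n_probes >= 1, var_x > 0, var_w > 0,
            link_sign %in% c(-1, 1))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  x <- matrix(stats::rnorm(n_probes * n_samples, mean_x, sqrt(var_x)),
              n_probes, n_samples)
  w <- matrix(stats::rnorm(n_probes * n_samples, 0, sqrt(var_w)),
              n_probes, n_samples)
  z <- link_sign * x + w
  rownames(x) <- paste0("x", seq_len(n_probes))
  rownames(z) <- paste0("z", seq_len(n_probes))
  colnames(x) <- colnames(z) <- paste0("s", seq_len(n_samples))
  list(X = x, Z = z,
       config = list(n_samples = n_samples, n_probes = n_probes,
                     mean_x = mean_x, var_x = var_x, var_w = var_w,
                     link_sign = link_sign, seed = seed))
}

#' Simulate covariate sets from a joint covariance matrix
#'
#' Draws samples from a zero-mean multivariate normal whose covariance over
#' the stacked `(X-block, Z-block)` is given, e.g. an empirical covariance
#' estimated from real cis-window covariates.  Useful for reproducing
#' realistic correlation structure between and within platforms.
#'
#' @param cov Symmetric positive semi-definite covariance matrix of
#'   dimension `n_x + n_z`.
#' @param n_x Number of leading rows/columns belonging to the X block.
#' @param n_samples Number of samples to draw.
#' @param seed Integer seed.
#' @return List with `X` (`n_x` probes x samples) and `Z` (the rest), plus
#'   the config.
#' @export
simulate_from_covariance <- function(cov, n_x, n_samples, seed = 42L) {
  cov <- as.matrix(cov)
  if (!isSymmetric(cov, tol = 1e-8)) stop("'cov' must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("'cov' is not positive semi-definite (smallest eigenvalue ",
         format(min(ev)), ")")
  if (n_x < 1 || n_x >= nrow(cov)) stop("'n_x' must split cov into two blocks")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  draws <- MASS::mvrnorm(n_samples, mu = rep(0, nrow(cov)), Sigma = cov)
  draws <- t(draws)                 # probes x samples
  colnames(draws) <- paste0("s", seq_len(n_samples))
  x <- draws[seq_len(n_x), , drop = FALSE]
  z <- draws[-seq_len(n_x), , drop = FALSE]
  rownames(x) <- paste0("x", seq_len(nrow(x)))
  rownames(z) <- paste0("z", seq_len(nrow(z)))
  list(X = x, Z = z,
       config = list(n_x = n_x, n_samples = n_samples, seed = seed))
}

#' Simulate responses under one association-region effect type
#'
#' Builds a matrix of response probes over the same samples as `X`, `Z`.
#' The first `n_associated` response probes carry a true association whose
#' form depends on the region type; the rest are pure noise.  Writing
#' `xbar_i` (`zbar_i`) for the mean of the covariate probes in a window of
#' half-width `effect_halfwidth` around matched index `i`:
#' \describe{
#'   \item{`x_only`}{`Y_i = b*xbar_i + e` — only the X set matters.}
#'   \item{`additive`}{`Y_i = b*xbar_i + b*zbar_i + e` — both sets act
#'     linearly.}
#'   \item{`multiplicative`}{`Y_i = b*xbar_i + b*zbar_i +
#'     b*xbar_i*zbar_i + e` — linear plus product term.}
#'   \item{`complementary`}{(split samples) `Y_i` depends on `xbar_i` for
#'     the first half of the samples and on `zbar_i` for the rest — two
#'     mechanisms acting in different sample subsets.}
#' }
#' The sample split for `complementary` is deterministic
#' (first `ceiling(N/2)` by column index).
#'
#' @param X,Z Covariate matrices (probes x samples), row-aligned by
#'   matched index.
#' @param region_type One of `"x_only"`, `"additive"`, `"multiplicative"`,
#'   `"complementary"`.
#' @param n_associated Number of leading response probes with a true
#'   effect (default half).
#' @param effect_size Linear effect coefficient `b` (default 0.5).
#' @param noise_sd Residual standard deviation (default 1).
#' @param effect_halfwidth Half-width of the covariate window feeding each
#'   response probe (default 2, i.e. up to 5 covariates).
#' @param seed Integer seed.
#' @return Object of class `simulated_study`: matrices `Y`, `X`, `Z`
#'   (probes x samples), logical `truth` per response probe, and `config`.
#' @export
simulate_region <- function(X, Z,
                            region_type = c("x_only", "additive",
                                            "multiplicative", "complementary"),
                            n_associated = floor(nrow(X) / 2),
                            effect_size = 0.5, noise_sd = 1,
                            effect_halfwidth = 2L, seed = 42L) {
  region_type <- match.arg(region_type)
  stopifnot(is.matrix(X), is.matrix(Z), ncol(X) == ncol(Z),
            nrow(X) == nrow(Z), noise_sd > 0)
  n_probes <- nrow(X); n <- ncol(X)
  if (n_associated > n_probes) stop("n_associated exceeds the number of probes")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  y <- matrix(stats::rnorm(n_probes * n, 0, noise_sd), n_probes, n)
  half <- ceiling(n / 2)
  for (i in seq_len(n_associated)) {
    win <- max(1L, i - effect_halfwidth):min(n_probes, i + effect_halfwidth)
    xbar <- colMeans(X[win, , drop = FALSE])
    zbar <- colMeans(Z[win, , drop = FALSE])
    signal <- switch(region_type,
      x_only = effect_size * xbar,
      additive = effect_size * (xbar + zbar),
      multiplicative = effect_size * (xbar + zbar + xbar * zbar),
      complementary = c(effect_size * xbar[seq_len(half)],
                        effect_size * zbar[(half + 1):n]))
    y[i, ] <- y[i, ] + signal
  }
  rownames(y) <- paste0("y", seq_len(n_probes))
  colnames(y) <- colnames(X)
  truth <- seq_len(n_probes) <= n_associated
  structure(
    list(Y = y, X = X, Z = Z, truth = truth,
         config = list(region_type = region_type, n_associated = n_associated,
                       effect_size = effect_size, noise_sd = noise_sd,
                       effect_halfwidth = effect_halfwidth, seed = seed)),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated study (%s): %d response probes x %d samples, %d associated\n",
              x$config$region_type, nrow(x$Y), ncol(x$Y), sum(x$truth)))
  invisible(x)
}

#' Write a simulated study to TSV files
#'
#' Writes `Y`, `X`, `Z` matrices, the truth labels and a key=value sidecar
#' recording the generating parameters, under `prefix`.
#'
#' @param study A [simulate_region()] result.
#' @param prefix Output path prefix (directories are created).
#' @return Invisibly, the vector of file paths written.
#' @export
write_study <- function(study, prefix) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dirname(paste0(prefix, "x")), recursive = TRUE, showWarnings = FALSE)
  paths <- c(Y = paste0(prefix, "Y.tsv"), X = paste0(prefix, "X.tsv"),
             Z = paste0(prefix, "Z.tsv"), truth = paste0(prefix, "truth.tsv"),
             config = paste0(prefix, "config.txt"))
  write_matrix(study$Y, paths["Y"])
  write_matrix(study$X, paths["X"])
  write_matrix(study$Z, paths["Z"])
  utils::write.table(
    data.frame(response_id = rownames(study$Y), truth = study$truth),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(names(study$config), unlist(study$config), sep = "="),
             paths["config"])
  invisible(paths)
}
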