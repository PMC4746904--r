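#' Fit the null model for a response
#'
#' The score test works with residuals from the model that contains no
#' covariate-set effects: an intercept plus any confounders, fitted by
#' ordinary least squares.  All statistics downstream are functions of
#' these residuals, so confounder adjustment amounts to residualizing the
#' response (and, internally, the covariates) on the null design.
#'
#' @param y Numeric response vector of length `N >= 3`.
#' @param confounders Optional numeric matrix (`N x p`) of confounders; an
#'   intercept is always included and must not be duplicated here.
#' @param sample_ids Optional character vector of sample identifiers
#'   (unique, length `N`).
#' @return An object of class `mgt_null` with elements `fitted`,
#'   `residuals`, `rss`, `df_resid`, `design_rank`, `n`, and the QR
#'   decomposition of the null design (used to project covariates onto the
#'   residual space).
#' @examples
#' nm <- fit_null(c(1, 2, 3, 4))
#' nm$residuals      # (-1.5, -0.5, 0.5, 1.5)
#' nm$df_resid       # 3
#' @export
fit_null <- function(y, confounders = NULL, sample_ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples")
  if (anyNA(y)) stop("response contains missing values")
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != n) stop("sample_ids length mismatch")
    if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  }
  design <- matrix(1, n, 1L)
  if (!is.null(confounders)) {
    confounders <- as.matrix(confounders)
    if (nrow(confounders) != n) stop("confounders must have one row per sample")
    if (anyNA(confounders)) stop("confounders contain missing values")
    design <- cbind(design, confounders)
  }
  qrd <- qr(design)
  if (qrd$rank + 1L > n)
    stop("null design leaves no residual degrees of freedom")
  fitted <- qr.fitted(qrd, y)
  res <- qr.resid(qrd, y)
  rss <- sum(res^2)
  # guard against a response fully explained by the null design
  if (rss < 1e-12 * n * max(stats::var(y), .Machine$double.eps))
    stop("degenerate response: residual variance is (numerically) zero")
  df_resid <- n - qrd$rank
  if (df_resid < 2L) stop("need residual degrees of freedom >= 2")
  structure(
    list(fitted = fitted, residuals = res, rss = rss,
         df_resid = df_resid, design_rank = qrd$rank, n = n,
         qr = qrd, sample_ids = sample_ids,
         has_confounders = !is.null(confounders)),
    class = "mgt_null"
  )
}

#' @export
print.mgt_null <- function(x, ...) {
  cat(sprintf("null model: %d samples, design rank %d, df_resid %d\n",
              x$n, x$design_rank, x$df_resid))
  invisible(x)
}

# Project columns of a matrix onto the residual space of the null design.
project_residual_space <- function(null, values) {
  qr.resid(null$qr, values)
}

check_alignment <- function(null, xset) {
  if (nrow(xset$values) != null$n)
    stop("covariate set '", xset$name, "' has ", nrow(xset$values),
         " rows but the null model has ", null$n, " samples")
  invisible(TRUE)
}
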