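#' Single-set global test statistic Q
#'
#' The unscaled variance-component score statistic for association between
#' the response and one covariate set:
#' \deqn{Q(X) = \frac{r^t X X^t r}{r^t r},}
#' where `r` are the null-model residuals.  Large values indicate that the
#' residuals line up with directions of high (co)variance in the set.  The
#' computation works in probe space (`||X^t r||^2 / r^t r`), so the `N x N`
#' matrix `X X^t` is never formed and genome-wide use stays cheap.
#'
#' @param null An [fit_null()] object.
#' @param xset A [covariate_set()] row-aligned with the null model.
#' @return A single number, `Q >= 0`.
#' @seealso [moments_q()], [joint_statistic()]
#' @export
q_statistic <- function(null, xset) {
  stopifnot(inherits(null, "mgt_null"), inherits(xset, "covariate_set"))
  check_alignment(null, xset)
  cross <- crossprod(xset$values, null$residuals)  # J x 1
  sum(cross^2) / null$rss
}

#' Null mean and variance of Q
#'
#' Moments of `Q` under the rotation-invariant null: the residual direction
#' is uniform on the unit sphere of the residual space (dimension
#' `d = df_resid`).  Writing `A` for `X X^t` projected onto that space,
#' \deqn{E[Q] = tr(A)/d, \qquad
#'       Var[Q] = \frac{2\,(d\,tr(A^2) - tr(A)^2)}{d^2 (d+2)}.}
#' Both traces are evaluated through the `J x J` Gram matrix of the
#' projected covariates.  These spherical moments also equal the exact
#' finite-sample moments under the gaussian linear model; they differ
#' slightly from exact permutation moments, which is why permutation
#' p-values remain the inferential default and the moments serve
#' standardization and diagnostics.
#'
#' @inheritParams q_statistic
#' @return List with `expected_q`, `var_q` and `trace_term` (`tr(A)`).
#'   `var_q` is `NA` (with a warning) when the set is constant on the
#'   residual space.
#' @export
moments_q <- function(null, xset) {
  stopifnot(inherits(null, "mgt_null"), inherits(xset, "covariate_set"))
  check_alignment(null, xset)
  xp <- project_residual_space(null, xset$values)
  g <- crossprod(xp)                      # J x J projected Gram
  tr_a <- sum(diag(g))
  tr_a2 <- sum(g * g)
  d <- null$df_resid
  expected_q <- tr_a / d
  var_q <- 2 * (d * tr_a2 - tr_a^2) / (d^2 * (d + 2))
  if (!is.finite(var_q) || var_q <= .Machine$double.eps * max(1, tr_a2)) {
    warning("covariate set '", xset$name,
            "' is constant on the residual space; T undefined")
    var_q <- NA_real_
  }
  list(expected_q = expected_q, var_q = var_q, trace_term = tr_a)
}

#' Standardized test statistic T
#'
#' Centers and scales `Q` by its null moments: `T = (Q - E[Q]) / sqrt(Var[Q])`.
#' `T` is invariant to rescaling the covariate set by a nonzero constant.
#'
#' @param q Observed statistic.
#' @param expected_q,var_q Null moments from [moments_q()].
#' @return A single number.
#' @export
standardized_t <- function(q, expected_q, var_q) {
  if (!is.finite(var_q) || var_q <= 0)
    stop("var_q must be positive to standardize Q")
  (q - expected_q) / sqrt(var_q)
}

#' Joint test statistic over multiple covariate sets
#'
#' Combines the per-set statistics of `M >= 1` covariate sets into one
#' joint statistic.  Three combination modes are supported:
#' \describe{
#'   \item{`sum`}{\eqn{\sum_m w_m Q_m} (default, unit weights).  With unit
#'     weights this equals the single-set statistic of the column-merged
#'     matrix, i.e. one variance-component test on all covariates pooled.}
#'   \item{`centered_squared`}{\eqn{\sum_m w_m (Q_m - E[Q_m])^2}, the
#'     squared norm of the (centered, unscaled) score vector.}
#'   \item{`standardized_sum`}{\eqn{\sum_m w_m T_m}, the sum of the
#'     standardized statistics; useful when sets differ strongly in scale
#'     or size.}
#' }
#' The per-set weight multiplies each set's contribution and realizes a
#' fixed prior ratio between the random-effect variances of the sets; it
#' must be chosen a priori.
#'
#' @param null An [fit_null()] object.
#' @param sets A [covariate_set()] or list of them, row-aligned with the
#'   null model.
#' @param mode Combination mode, see Details.
#' @param weights Optional numeric vector of per-set weights overriding the
#'   sets' own weights (recycled checkably; default: each set's `weight`).
#' @param standardize Center and unit-scale each covariate column before
#'   testing (default `FALSE`; raw covariate scales then contribute to the
#'   statistic).
#' @return An object of class `mgt_result`: per-set components (`q`,
#'   `expected_q`, `var_q`, `t`, `trace_term`, `set_sizes`, `weights`), the
#'   `combined` statistic, `combine_mode`, p-value slots (`NA` until filled
#'   by a null-distribution method) and `flags`.
#' @examples
#' set.seed(1)
#' nm <- fit_null(rnorm(12))
#' cs <- covariate_set(matrix(rnorm(36), 12, 3), name = "CN")
#' joint_statistic(nm, cs)$combined == q_statistic(nm, cs)
#' @export
joint_statistic <- function(null, sets,
                            mode = c("sum", "centered_squared", "standardized_sum"),
                            weights = NULL, standardize = FALSE) {
  stopifnot(inherits(null, "mgt_null"))
  mode <- match.arg(mode)
  sets <- as_covariate_sets(sets)
  if (!is.null(weights)) {
    if (length(weights) != length(sets))
      stop("'weights' must have one entry per set")
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("'weights' must be positive")
    for (m in seq_along(sets)) sets[[m]]$weight <- weights[m]
  }
  if (standardize) {
    for (m in seq_along(sets))
      sets[[m]]$values <- standardize_columns(sets[[m]]$values)
  }
  flags <- character(0)
  w <- vapply(sets, `[[`, numeric(1L), "weight")
  q <- expected_q <- var_q <- tval <- trace_term <- numeric(length(sets))
  names(q) <- names(sets)
  for (m in seq_along(sets)) {
    check_alignment(null, sets[[m]])
    q[m] <- q_statistic(null, sets[[m]])
    mom <- withCallingHandlers(
      moments_q(null, sets[[m]]),
      warning = function(wng) {
        flags <<- c(flags, paste0("constant_on_residual_space:", names(sets)[m]))
        invokeRestart("muffleWarning")
      })
    expected_q[m] <- mom$expected_q
    var_q[m] <- mom$var_q
    trace_term[m] <- mom$trace_term
    tval[m] <- if (is.finite(mom$var_q) && mom$var_q > 0)
      standardized_t(q[m], mom$expected_q, mom$var_q) else NA_real_
    if (all(abs(sets[[m]]$values) < .Machine$double.eps))
      flags <- c(flags, paste0("zero_set:", names(sets)[m]))
  }
  names(expected_q) <- names(var_q) <- names(tval) <- names(trace_term) <- names(sets)
  combined <- switch(mode,
    sum = sum(w * q),
    centered_squared = sum(w * (q - expected_q)^2),
    standardized_sum = {
      if (anyNA(tval)) {
        flags <- c(flags, "standardized_sum_dropped_degenerate_sets")
        sum(w[!is.na(tval)] * tval[!is.na(tval)])
      } else sum(w * tval)
    })
  structure(
    list(components = list(q = q, expected_q = expected_q, var_q = var_q,
                           t = tval, trace_term = trace_term),
         combined = combined, combine_mode = mode,
         set_sizes = vapply(sets, function(s) ncol(s$values), integer(1L)),
         weights = stats::setNames(w, names(sets)),
         p_per_set = stats::setNames(rep(NA_real_, length(sets)), names(sets)),
         p_joint = NA_real_,
         flags = unique(flags)),
    class = "mgt_result"
  )
}

#' @export
print.mgt_result <- function(x, ...) {
  cat(sprintf("multi-set global test (%s): combined = %.5g\n",
              x$combine_mode, x$combined))
  comp <- data.frame(set = names(x$components$q),
                     J = unname(x$set_sizes),
                     Q = unname(x$components$q),
                     T = unname(x$components$t),
                     p = unname(x$p_per_set))
  print(comp, row.names = FALSE, digits = 4)
  if (!is.na(x$p_joint)) cat(sprintf("joint p-value: %.4g\n", x$p_joint))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
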