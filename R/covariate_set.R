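#' Construct a covariate set
#'
#' A covariate set is a named group of measurements tested jointly for
#' association with a response: for example, all copy-number probes within a
#' cis window around one gene.  The set carries an `N x J` matrix of values
#' (samples in rows), probe identifiers, optional genomic positions and a
#' positive prior weight used when several sets are combined into a joint
#' statistic.
#'
#' @param values Numeric matrix, samples in rows (`N x J`).  A vector is
#'   treated as a single-column matrix.
#' @param name Set label, e.g. `"CN"` or `"ME"`.
#' @param probe_ids Character vector of length `J`; defaults to column names
#'   or `probe1..probeJ`.
#' @param positions Optional `data.frame` with columns `chrom` and `pos`
#'   (one row per probe, base pairs).
#' @param weight Positive scalar weight given to this set in joint
#'   statistics (default 1, equal prior weight for all sets).
#' @param impute_missing Replace missing values by their probe (column)
#'   mean, with a warning.  Default `FALSE`: missing values are an error.
#' @return An object of class `covariate_set`.
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' cs <- covariate_set(x, name = "CN")
#' ncol(cs$values)
#' @export
covariate_set <- function(values, name = "set", probe_ids = NULL,
                          positions = NULL, weight = 1,
                          impute_missing = FALSE) {
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, ncol = 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples in rows)")
  if (anyNA(values)) {
    if (!impute_missing)
      stop("covariate set '", name, "' contains missing values; ",
           "impute or drop probes first (or set impute_missing = TRUE)")
    n_miss <- sum(is.na(values))
    cm <- colMeans(values, na.rm = TRUE)
    bad <- which(is.na(values), arr.ind = TRUE)
    values[bad] <- cm[bad[, 2L]]
    if (anyNA(values))
      stop("covariate set '", name, "' has probes with no observed values")
    warning("covariate set '", name, "': imputed ", n_miss,
            " missing value(s) by probe means")
  }
  if (ncol(values) < 1L) stop("covariate set '", name, "' has no probes (J = 0)")
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop("'weight' must be a single positive number")
  if (is.null(probe_ids)) {
    probe_ids <- colnames(values)
    if (is.null(probe_ids)) probe_ids <- paste0("probe", seq_len(ncol(values)))
  }
  if (length(probe_ids) != ncol(values))
    stop("length(probe_ids) must equal ncol(values)")
  if (!is.null(positions)) {
    if (!is.data.frame(positions) || nrow(positions) != ncol(values))
      stop("'positions' must be a data.frame with one row per probe")
    if (!all(c("chrom", "pos") %in% names(positions)))
      stop("'positions' needs columns 'chrom' and 'pos'")
  }
  colnames(values) <- probe_ids
  structure(
    list(name = name, values = values, probe_ids = probe_ids,
         positions = positions, weight = weight),
    class = "covariate_set"
  )
}

#' @export
print.covariate_set <- function(x, ...) {
  cat(sprintf("covariate set '%s': %d samples x %d probes, weight %g\n",
              x$name, nrow(x$values), ncol(x$values), x$weight))
  invisible(x)
}

# Center (and optionally scale) each probe column; constant columns are left
# centered at zero rather than producing NaN.
standardize_columns <- function(values, scale = TRUE) {
  values <- sweep(values, 2L, colMeans(values), "-")
  if (scale) {
    s <- apply(values, 2L, stats::sd)
    s[s < .Machine$double.eps^0.5] <- 1
    values <- sweep(values, 2L, s, "/")
  }
  values
}

as_covariate_sets <- function(sets) {
  if (inherits(sets, "covariate_set")) sets <- list(sets)
  if (!length(sets)) stop("at least one covariate set is required")
  ok <- vapply(sets, inherits, logical(1L), what = "covariate_set")
  if (!all(ok)) stop("'sets' must be a covariate_set or a list of them")
  nm <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("covariate set names must be unique")
  names(sets) <- nm
  sets
}
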