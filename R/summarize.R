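#' Select associations at a p-value threshold
#'
#' Marks p-values at or below `alpha` as selected (closed comparison, so a
#' p-value exactly at the threshold is selected).  Selection is done on raw
#' p-values by default throughout the package, because comparisons between
#' tests and data sets are cleaner on the uncorrected scale; use
#' [fdr_adjust()] first when a corrected selection is wanted.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @param alpha Threshold in `(0, 1)`, e.g. `0.001` for genome-wide probe
#'   selection.
#' @return Logical vector, `TRUE` where `p <= alpha`.
#' @export
select_associations <- function(p, alpha) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0, 1]")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  p <= alpha
}

#' Overlap, new-discovery and dilution ratios
#'
#' Compares selections by the joint test with selections by one individual
#' test:
#' \describe{
#'   \item{overlap}{fraction of joint-selected responses also selected by
#'     the individual test (relative to all selected joint tests);}
#'   \item{new_disc}{`1 - overlap` — the joint test's new discoveries;}
#'   \item{dilution}{fraction of individually selected responses missed by
#'     the joint test (relative to all selected individual tests) — the
#'     price of pooling a strong single-set effect with an uninformative
#'     set.}
#' }
#' A ratio whose denominator is zero is reported as `NA`, never as 0.
#'
#' @param sel_joint,sel_individual Logical selection vectors of equal
#'   length (one element per response probe).
#' @return List with `overlap`, `new_disc`, `dilution` and the backing
#'   `counts` (`n_joint`, `n_individual`, `n_both`).
#' @examples
#' overlap_ratios(c(TRUE, TRUE, TRUE, TRUE, FALSE),
#'                c(FALSE, FALSE, TRUE, TRUE, TRUE))
#' @export
overlap_ratios <- function(sel_joint, sel_individual) {
  stopifnot(is.logical(sel_joint), is.logical(sel_individual),
            length(sel_joint) == length(sel_individual))
  n_joint <- sum(sel_joint, na.rm = TRUE)
  n_ind <- sum(sel_individual, na.rm = TRUE)
  n_both <- sum(sel_joint & sel_individual, na.rm = TRUE)
  overlap <- if (n_joint > 0) n_both / n_joint else NA_real_
  new_disc <- if (n_joint > 0) 1 - overlap else NA_real_
  dilution <- if (n_ind > 0) sum(sel_individual & !sel_joint, na.rm = TRUE) / n_ind
              else NA_real_
  list(overlap = overlap, new_disc = new_disc, dilution = dilution,
       counts = c(n_joint = n_joint, n_individual = n_ind, n_both = n_both))
}

#' ROC curve and AUC for a p-value ranking
#'
#' Sweeps selection thresholds over the unique p-values (ties grouped) and
#' returns false/true positive rates plus the area under the curve.  The
#' AUC is computed as the Mann-Whitney probability that a truly associated
#' response receives a smaller p-value than a null one, with ties counted
#' one half — identical to the trapezoid area over the tie-grouped curve.
#'
#' @param p Numeric p-values (smaller = more significant).
#' @param truth Logical ground-truth labels, at least one `TRUE` and one
#'   `FALSE`.
#' @return List with `points` (`data.frame` of `threshold`, `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(p, truth) {
  stopifnot(length(p) == length(truth), is.logical(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("'truth' must contain at least one TRUE and one FALSE")
  thr <- sort(unique(p))
  tpr <- vapply(thr, function(t) sum(p[truth] <= t) / n1, numeric(1L))
  fpr <- vapply(thr, function(t) sum(p[!truth] <= t) / n0, numeric(1L))
  points <- data.frame(threshold = c(0, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  # Mann-Whitney with ties at 1/2 (ranks of -p so that small p ranks high)
  r <- rank(-p)
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(points = points, auc = auc)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a convenience wrapper kept here
#' so summaries can switch between raw and FDR-adjusted selection.
#'
#' @param p Numeric p-values in `(0, 1]`.
#' @return Adjusted p-values (monotone in the ranks of `p`, capped at 1).
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Summarize a genome-wide results table
#'
#' Applies threshold selection to the joint and individual test p-values
#' and computes the overlap/new-discovery/dilution ratios genome-wide and,
#' when an `arm` column is present, per chromosome arm.
#'
#' @param results `data.frame` from [run_genomewide()] with columns
#'   `p_joint` and one `p_<set>` column per covariate set, optionally
#'   `arm`.
#' @param alpha Selection threshold (default 0.001).
#' @param use_fdr Adjust each p-value column by [fdr_adjust()] before
#'   selection (default `FALSE`, matching raw-p selection).
#' @return List with `selection` (the input plus `sel_*` logical columns),
#'   `ratios` (`data.frame` with one row per (scope, set): overlap,
#'   new_disc, dilution and counts; scope is `"genomewide"` or an arm
#'   label) and `alpha`.
#' @export
summarize_selection <- function(results, alpha = 0.001, use_fdr = FALSE) {
  stopifnot(is.data.frame(results), "p_joint" %in% names(results))
  pcols <- grep("^p_", names(results), value = TRUE)
  ind_cols <- setdiff(pcols, "p_joint")
  sel <- results
  for (pc in pcols) {
    pv <- if (use_fdr) fdr_adjust(results[[pc]]) else results[[pc]]
    sel[[sub("^p_", "sel_", pc)]] <- select_associations(pv, alpha)
  }
  scopes <- list(genomewide = rep(TRUE, nrow(sel)))
  if ("arm" %in% names(sel) && !all(is.na(sel$arm))) {
    for (a in sort(unique(stats::na.omit(sel$arm))))
      scopes[[a]] <- !is.na(sel$arm) & sel$arm == a
  }
  rows <- list()
  for (scope in names(scopes)) {
    keep <- scopes[[scope]]
    for (ic in ind_cols) {
      r <- overlap_ratios(sel$sel_joint[keep], sel[[sub("^p_", "sel_", ic)]][keep])
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, set = sub("^p_", "", ic),
        overlap = r$overlap, new_disc = r$new_disc, dilution = r$dilution,
        n_joint = r$counts["n_joint"], n_individual = r$counts["n_individual"],
        n_both = r$counts["n_both"], row.names = NULL)
    }
  }
  list(selection = sel, ratios = do.call(rbind, rows), alpha = alpha,
       use_fdr = use_fdr)
}
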