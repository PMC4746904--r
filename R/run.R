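#' Genome-wide joint and individual covariate-set tests
#'
#' For every response probe with a gene annotation, builds the cis-window
#' covariate sets on each platform, fits the null model, and computes the
#' individual per-set statistics and the joint statistic together with
#' their p-values.  One permutation stream (from `seed`) is shared by all
#' responses, so results are identical under any execution order and
#' p-values are comparable across responses.
#'
#' @param response Numeric matrix of responses, probes in rows, samples in
#'   columns (ids in dimnames); row names must match `genes$feature_id`.
#' @param genes Gene annotation `data.frame` as from [read_gene_bed()]
#'   (`feature_id`, `chrom`, `tss`, optional `arm`).
#' @param covsets Named list, one element per covariate platform, each a
#'   list with `values` (probes x samples matrix), `probes` (annotation as
#'   from [read_probe_bed()]), `flank_bp` and optionally `weight`.
#' @param mode Combination mode, see [joint_statistic()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the shared permutation stream.
#' @param pvalue_method `"permutation"` (default), `"asymptotic"` (only
#'   with `mode = "sum"`), or `"both"`.
#' @param alpha Selection threshold recorded with the run (used by
#'   [summarize_selection()]).
#' @param standardize Center/scale covariate columns before testing.
#' @param confounders Optional `N x p` confounder matrix (rows aligned to
#'   the shared samples after id alignment).
#' @param log_path Optional JSON-lines log file.
#' @return `data.frame` with one row per testable response probe:
#'   `response_id`, `arm`, per-set sizes `n_<set>`, statistics `q_<set>`,
#'   p-values `p_<set>`, `q_joint`, `p_joint` (and `p_joint_asym` /
#'   `p_<set>_asym` when requested) and semicolon-collapsed `flags`.
#'   The run settings are attached as the `config` attribute.
#' @export
run_genomewide <- function(response, genes, covsets,
                           mode = c("sum", "centered_squared", "standardized_sum"),
                           n_perm = 999L, seed = 42L,
                           pvalue_method = c("permutation", "asymptotic", "both"),
                           alpha = 0.001, standardize = FALSE,
                           confounders = NULL, log_path = NULL) {
  mode <- match.arg(mode)
  pvalue_method <- match.arg(pvalue_method)
  if (pvalue_method != "permutation" && mode != "sum")
    stop("asymptotic p-values require mode = 'sum'")
  stopifnot(is.matrix(response), length(covsets) >= 1L)
  if (is.null(names(covsets)) || any(!nzchar(names(covsets))))
    stop("'covsets' must be a named list")
  t0 <- proc.time()[["elapsed"]]

  aligned <- align_samples(c(list(response = response),
                             lapply(covsets, `[[`, "values")))
  response <- aligned[[1L]]
  for (m in seq_along(covsets)) covsets[[m]]$values <- aligned[[m + 1L]]
  n <- ncol(response)
  log_event(log_path, "config", n_samples = n, n_responses = nrow(response),
            sets = names(covsets), mode = mode, n_perm = n_perm, seed = seed,
            pvalue_method = pvalue_method, alpha = alpha,
            standardize = standardize,
            dropped_samples = attr(aligned, "dropped"))

  genes <- genes[genes$feature_id %in% rownames(response), , drop = FALSE]
  if (!nrow(genes)) stop("no response probe has a gene annotation")
  windows <- lapply(covsets, function(cs)
    build_sets(genes, cs$probes, cs$flank_bp))
  log_event(log_path, "windows",
            empty_per_set = lapply(windows, function(w) length(attr(w, "empty"))))

  plan <- permutation_plan(n_perm = n_perm, seed = seed)
  idx <- permutation_indices(n, plan,
                             exhaustive_ok = is.null(confounders))
  set_names <- names(covsets)
  do_perm <- pvalue_method %in% c("permutation", "both")
  do_asym <- pvalue_method %in% c("asymptotic", "both")

  rows <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gid <- genes$feature_id[g]
    flags <- character(0)
    sets <- list()
    sizes <- stats::setNames(integer(length(covsets)), set_names)
    for (m in seq_along(covsets)) {
      pidx <- windows[[m]][[gid]]
      sizes[m] <- length(pidx)
      if (!length(pidx)) {
        flags <- c(flags, paste0("empty_set:", set_names[m]))
        next
      }
      sets[[set_names[m]]] <- covariate_set(
        t(covsets[[m]]$values[pidx, , drop = FALSE]),
        name = set_names[m],
        probe_ids = covsets[[m]]$probes$probe_id[pidx],
        weight = if (is.null(covsets[[m]]$weight)) 1 else covsets[[m]]$weight)
    }
    row <- data.frame(response_id = gid,
                      arm = if ("arm" %in% names(genes)) genes$arm[g] else NA,
                      stringsAsFactors = FALSE)
    for (s in set_names) row[[paste0("n_", s)]] <- sizes[[s]]
    qcols <- c(paste0("q_", set_names), "q_joint")
    pcols <- c(paste0("p_", set_names), "p_joint")
    for (cn in c(qcols, pcols)) row[[cn]] <- NA_real_
    if (do_asym) for (cn in paste0(pcols, "_asym")) row[[cn]] <- NA_real_

    if (length(sets)) {
      nullm <- tryCatch(fit_null(response[gid, ], confounders = confounders),
                        error = function(e) NULL)
      if (is.null(nullm)) {
        flags <- c(flags, "degenerate_response")
      } else {
        res <- joint_statistic(nullm, sets, mode = mode,
                               standardize = standardize)
        flags <- c(flags, res$flags)
        row$q_joint <- res$combined
        for (s in names(sets)) row[[paste0("q_", s)]] <- res$components$q[[s]]
        if (do_perm) {
          p <- permutation_pvalue(nullm, sets, mode = mode,
                                  standardize = standardize,
                                  plan = plan, idx = idx)
          row$p_joint <- as.numeric(p)
          pps <- attr(p, "p_per_set")
          for (s in names(sets)) row[[paste0("p_", s)]] <- pps[[s]]
        }
        if (do_asym) {
          spec <- spectral_null(nullm, sets, standardize = standardize)
          row$p_joint_asym <- asymptotic_pvalue(res$combined, spec)
          for (s in names(sets)) {
            spec_s <- spectral_null(nullm, sets[s], standardize = standardize)
            row[[paste0("p_", s, "_asym")]] <-
              asymptotic_pvalue(res$components$q[[s]], spec_s)
          }
        }
      }
    } else {
      flags <- c(flags, "no_testable_set")
    }
    row$flags <- paste(unique(flags), collapse = ";")
    rows[[g]] <- row
  }
  out <- do.call(rbind, rows)
  if (all(is.na(out$q_joint))) stop("no testable response probes")
  attr(out, "config") <- list(mode = mode, n_perm = n_perm, seed = seed,
                              pvalue_method = pvalue_method, alpha = alpha,
                              standardize = standardize,
                              flank_bp = lapply(covsets, `[[`, "flank_bp"))
  log_event(log_path, "done", n_rows = nrow(out),
            elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  out
}

#' File-based genome-wide run
#'
#' Thin wrapper over [run_genomewide()] reading all inputs from disk: the
#' response matrix, one matrix + BED annotation per covariate platform, and
#' the gene BED.  Intended for scripted/CLI use.
#'
#' @param config Named list (or path to a `key=value` file readable by
#'   [read_run_config()]) with keys `response`, `genes`, per-platform
#'   `<name>_matrix`, `<name>_annotation`, `<name>_flank` (and optional
#'   `<name>_weight`), plus any of `mode`, `n_perm`, `seed`, `alpha`,
#'   `pvalue_method`, `standardize`, `out_prefix`, `log`.
#' @return The results `data.frame`; when `out_prefix` is set, also writes
#'   `<prefix>results.tsv`, `<prefix>ratios.tsv` and `<prefix>selection.tsv`.
#' @export
run_genomewide_files <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  need <- c("response", "genes")
  if (!all(need %in% names(config)))
    stop("config needs keys: ", paste(need, collapse = ", "))
  response <- read_matrix(config$response)
  genes <- read_gene_bed(config$genes)
  plat <- unique(sub("_matrix$", "", grep("_matrix$", names(config), value = TRUE)))
  if (!length(plat)) stop("config defines no '<name>_matrix' platform")
  covsets <- list()
  for (p in plat) {
    covsets[[p]] <- list(
      values = read_matrix(config[[paste0(p, "_matrix")]]),
      probes = read_probe_bed(config[[paste0(p, "_annotation")]]),
      flank_bp = as.numeric(config[[paste0(p, "_flank")]]),
      weight = if (!is.null(config[[paste0(p, "_weight")]]))
        as.numeric(config[[paste0(p, "_weight")]]) else 1)
  }
  get <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  res <- run_genomewide(
    response, genes, covsets,
    mode = get("mode", "sum"),
    n_perm = as.integer(get("n_perm", 999L)),
    seed = as.integer(get("seed", 42L)),
    pvalue_method = get("pvalue_method", "permutation"),
    alpha = get("alpha", 0.001),
    standardize = isTRUE(get("standardize", FALSE)),
    log_path = get("log", NULL))
  prefix <- get("out_prefix", NULL)
  if (!is.null(prefix)) {
    dir.create(dirname(paste0(prefix, "x")), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res, paste0(prefix, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summ <- summarize_selection(res, alpha = get("alpha", 0.001))
    utils::write.table(summ$ratios, paste0(prefix, "ratios.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summ$selection, paste0(prefix, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
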