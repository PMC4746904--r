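#' Write a miniature on-disk study for examples and tests
#'
#' Generates a complete toy input bundle: 20 samples, 50 response probes
#' (one gene each) on two chromosome arms, a copy-number-like platform (80
#' probes, tested with a 1 Mb flank) and a methylation-like platform (60
#' probes, 50 Kb flank), with BED annotations and a run configuration
#' file.  A subset of genes carries a true copy-number association and a
#' smaller subset a methylation association, so end-to-end runs on the
#' fixture produce signal as well as null probes.  Output is deterministic
#' given `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named list of the paths written.
#' @export
make_fixtures <- function(dir, seed = 42L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- 20L
  samples <- sprintf("s%02d", seq_len(n))

  # genes: 25 on 20q, 25 on 13q, TSS spaced 400 Kb apart
  genes <- data.frame(
    chrom = rep(c("20", "13"), each = 25L),
    tss = rep(seq(1e6, by = 4e5, length.out = 25L), 2L),
    feature_id = sprintf("gene%02d", 1:50),
    strand = rep(c("+", "-"), 25L),
    arm = rep(c("20q", "13q"), each = 25L))

  # CN platform: 40 probes per chromosome, every 250 Kb
  cn_probes <- data.frame(
    probe_id = sprintf("cn%03d", 1:80),
    chrom = rep(c("20", "13"), each = 40L),
    pos = rep(seq(8e5, by = 2.5e5, length.out = 40L), 2L))
  # ME platform: one probe 10 Kb upstream of each TSS (so every gene's
  # 50 Kb window is nonempty) plus 5 scattered probes per chromosome
  me_pos <- c(genes$tss[1:25] - 1e4, seq(2e6, by = 1.7e6, length.out = 5L))
  me_probes <- data.frame(
    probe_id = sprintf("me%03d", 1:60),
    chrom = rep(c("20", "13"), each = 30L),
    pos = rep(me_pos, 2L))

  # copy number is segmental: per-sample arm-level gain/loss shared by all
  # probes on the arm, plus probe-level noise around the diploid value
  arm_gain <- matrix(stats::rnorm(2 * n, 0, 0.5), 2, n)
  cn <- 2 + arm_gain[rep(1:2, each = 40L), ] +
    matrix(stats::rnorm(80 * n, 0, 0.3), 80, n)
  dimnames(cn) <- list(cn_probes$probe_id, samples)
  me <- matrix(stats::rnorm(60 * n, 0, 1), 60, n,
               dimnames = list(me_probes$probe_id, samples))

  # responses: genes 1-10 track their cis CN window, 11-15 track ME, rest null
  y <- matrix(stats::rnorm(50 * n, 0, 1), 50, n,
              dimnames = list(genes$feature_id, samples))
  cn_sets <- build_sets(genes, cn_probes, flank_bp = 1e6)
  me_sets <- build_sets(genes, me_probes, flank_bp = 5e4)
  for (i in 1:10) {
    idx <- cn_sets[[i]]
    if (length(idx)) y[i, ] <- y[i, ] + 1.5 * colMeans(cn[idx, , drop = FALSE])
  }
  for (i in 11:15) {
    idx <- me_sets[[i]]
    if (length(idx)) y[i, ] <- y[i, ] + 1.5 * colMeans(me[idx, , drop = FALSE])
  }

  paths <- list(
    response = file.path(dir, "expression.tsv"),
    cn_matrix = file.path(dir, "cn.tsv"),
    me_matrix = file.path(dir, "me.tsv"),
    genes = file.path(dir, "genes.bed"),
    cn_annotation = file.path(dir, "cn_probes.bed"),
    me_annotation = file.path(dir, "me_probes.bed"),
    config = file.path(dir, "run.cfg"),
    truth = file.path(dir, "truth.tsv"))
  write_matrix(y, paths$response)
  write_matrix(cn, paths$cn_matrix)
  write_matrix(me, paths$me_matrix)
  # BED: 0-based start so that tss = start + 1 ('+'/'.') or end ('-')
  bed_start <- ifelse(genes$strand == "-", genes$tss - 1000L, genes$tss - 1L)
  bed_end <- ifelse(genes$strand == "-", genes$tss, genes$tss + 999L)
  utils::write.table(
    data.frame(genes$chrom, bed_start, bed_end, genes$feature_id, 0L,
               genes$strand, genes$arm),
    paths$genes, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (pp in list(list(cn_probes, paths$cn_annotation),
                  list(me_probes, paths$me_annotation))) {
    utils::write.table(
      data.frame(pp[[1L]]$chrom, pp[[1L]]$pos - 1L, pp[[1L]]$pos,
                 pp[[1L]]$probe_id),
      pp[[2L]], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(
    data.frame(response_id = genes$feature_id, truth = seq_len(50) <= 15),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    paste0("response=", paths$response),
    paste0("genes=", paths$genes),
    paste0("cn_matrix=", paths$cn_matrix),
    paste0("cn_annotation=", paths$cn_annotation),
    "cn_flank=1000000",
    paste0("me_matrix=", paths$me_matrix),
    paste0("me_annotation=", paths$me_annotation),
    "me_flank=50000",
    "mode=sum", "n_perm=199", paste0("seed=", seed), "alpha=0.05",
    "pvalue_method=permutation"),
    paths$config)
  invisible(paths)
}
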