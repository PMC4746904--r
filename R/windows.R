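#' Map probes to genes by symmetric cis windows around the TSS
#'
#' For each gene, collects the probes lying on the same chromosome within
#' `flank_bp` base pairs of the gene's transcription start site on either
#' side (closed interval: probes exactly at the boundary are included, and
#' strand never affects membership).  Typical flanks are 1 Mb for
#' copy-number platforms and 50 Kb for methylation platforms, reflecting
#' the reach of cis-regulatory effects.
#'
#' @param genes `data.frame` with columns `feature_id`, `chrom`, `tss`
#'   (1-based bp) and optionally `strand` and `arm`; see [read_gene_bed()].
#' @param probes `data.frame` with columns `probe_id`, `chrom`, `pos`
#'   (1-based bp); see [read_probe_bed()].
#' @param flank_bp Positive window half-width in base pairs.
#' @return Named list (one element per gene, in input order) of integer
#'   indices into `probes`, sorted by ascending position with ties broken
#'   by `probe_id`.  Genes with no probe in the window get an empty vector
#'   and are listed in the `empty` attribute; they are never dropped.
#'   Probes on chromosomes absent from `genes` are excluded with a warning.
#' @examples
#' genes <- data.frame(feature_id = "g1", chrom = "20", tss = 1e6)
#' probes <- data.frame(probe_id = c("a", "b"), chrom = "20",
#'                      pos = c(950000, 949999))
#' build_sets(genes, probes, flank_bp = 50000)
#' @export
build_sets <- function(genes, probes, flank_bp) {
  if (!all(c("feature_id", "chrom", "tss") %in% names(genes)))
    stop("'genes' needs columns feature_id, chrom, tss")
  if (!all(c("probe_id", "chrom", "pos") %in% names(probes)))
    stop("'probes' needs columns probe_id, chrom, pos")
  if (!is.numeric(flank_bp) || length(flank_bp) != 1L || flank_bp <= 0)
    stop("'flank_bp' must be a single positive number")
  if (anyDuplicated(genes$feature_id))
    stop("duplicate feature_id in 'genes'")
  gchrom <- normalize_chrom(genes$chrom)
  pchrom <- normalize_chrom(probes$chrom)
  unknown <- !(pchrom %in% unique(gchrom))
  if (any(unknown)) {
    warning(sum(unknown), " probe(s) on chromosomes absent from the gene ",
            "annotation were excluded: ",
            paste(unique(probes$chrom[unknown]), collapse = ", "))
  }
  usable <- which(!unknown)
  # pre-sort probes by (position, probe_id) once; membership preserves order
  ord <- usable[order(probes$pos[usable], probes$probe_id[usable])]
  out <- vector("list", nrow(genes))
  names(out) <- genes$feature_id
  empty <- character(0)
  by_chrom <- split(ord, pchrom[ord])
  for (i in seq_len(nrow(genes))) {
    cand <- by_chrom[[gchrom[i]]]
    if (is.null(cand)) cand <- integer(0)
    hit <- cand[abs(probes$pos[cand] - genes$tss[i]) <= flank_bp]
    out[[i]] <- hit
    if (!length(hit)) empty <- c(empty, genes$feature_id[i])
  }
  attr(out, "empty") <- empty
  attr(out, "flank_bp") <- flank_bp
  out
}

#' Read a BED-like gene annotation
#'
#' Expects a headerless tab-separated file with columns chrom, start, end,
#' feature_id, score (ignored), strand, and optionally a chromosome-arm
#' label in column 7.  BED coordinates are 0-based half-open; the TSS is
#' taken as `start + 1` for `+`/`.` strands and `end` for `-` strands.
#'
#' @param path File path.
#' @return `data.frame` with columns `feature_id`, `chrom`, `tss`,
#'   `strand`, `arm`.
#' @export
read_gene_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("gene BED needs at least 4 columns")
  strand <- if (ncol(d) >= 6L) as.character(d[[6L]]) else rep(".", nrow(d))
  strand[!strand %in% c("+", "-", ".")] <- "."
  tss <- ifelse(strand == "-", as.integer(d[[3L]]), as.integer(d[[2L]]) + 1L)
  arm <- if (ncol(d) >= 7L) as.character(d[[7L]]) else NA_character_
  out <- data.frame(feature_id = as.character(d[[4L]]),
                    chrom = as.character(d[[1L]]),
                    tss = tss, strand = strand, arm = arm,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$feature_id))
    stop("duplicate feature_id in ", path)
  out
}

#' Read a BED-like probe annotation
#'
#' Headerless tab-separated columns chrom, start, end, probe_id.  The probe
#' position is the interval midpoint converted to a 1-based coordinate
#' (`start + 1` for point probes of width one).
#'
#' @param path File path.
#' @return `data.frame` with columns `probe_id`, `chrom`, `pos`.
#' @export
read_probe_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("probe BED needs at least 4 columns")
  start1 <- as.numeric(d[[2L]]) + 1
  end <- as.numeric(d[[3L]])
  pos <- as.integer(floor((start1 + pmax(end, start1)) / 2))
  out <- data.frame(probe_id = as.character(d[[4L]]),
                    chrom = as.character(d[[1L]]),
                    pos = pos, stringsAsFactors = FALSE)
  if (anyDuplicated(out$probe_id))
    stop("duplicate probe_id in ", path)
  out
}
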