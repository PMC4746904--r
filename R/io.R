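#' Read a feature-by-sample matrix from TSV
#'
#' Matrices are stored features-in-rows, as distributed by array pipelines:
#' the first column holds feature (probe) identifiers and the header row
#' holds sample identifiers.
#'
#' @param path File path.
#' @return Numeric matrix with feature row names and sample column names.
#' @export
read_matrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop(path, ": need an id column plus at least one sample")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids))
    stop(path, ": duplicate feature id '", ids[duplicated(ids)][1L], "'")
  vals <- d[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad))
        stop(path, ": non-numeric value '", v[bad[1L]], "' at feature '",
             ids[bad[1L]], "', sample '", names(vals)[j], "'")
      vals[[j]] <- as.numeric(v)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' Inverse of [read_matrix()]: first column `feature_id`, then one column
#' per sample.  Values are written at full precision so a read/write cycle
#' is bit-identical.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  d <- data.frame(feature_id = rownames(m),
                  format(m, digits = 17, trim = TRUE, scientific = FALSE),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align matrices on their shared samples
#'
#' Sample alignment is identifier-driven, never positional: the shared
#' sample ids are taken in the order of the first (response) matrix and
#' every matrix is reduced to those columns.  Dropped samples are reported.
#'
#' @param ... Two or more feature-by-sample matrices with sample ids as
#'   column names.
#' @param min_shared Minimum number of shared samples (default 3).
#' @return List of matrices restricted to the shared samples, with a
#'   `dropped` attribute naming per-matrix dropped sample ids.
#' @export
align_samples <- function(..., min_shared = 3L) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]))
    mats <- mats[[1L]]
  stopifnot(length(mats) >= 2L)
  shared <- Reduce(intersect, lapply(mats, colnames))
  shared <- colnames(mats[[1L]])[colnames(mats[[1L]]) %in% shared]
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared samples across inputs (need >= ",
         min_shared, ")")
  dropped <- lapply(mats, function(m) setdiff(colnames(m), shared))
  out <- lapply(mats, function(m) m[, shared, drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Read a flat key=value run configuration
#'
#' One `key=value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric, `true`/`false` become
#' logical.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop(path, ": malformed line '", lines[bad][1L], "'")
  keys <- trimws(vapply(kv, `[[`, character(1L), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1L)))
  parse1 <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  stats::setNames(lapply(vals, parse1), keys)
}

# JSON-lines run log: one object per event, appended.
log_event <- function(log_path, event, ...) {
  if (is.null(log_path)) return(invisible(NULL))
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event = event),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
  invisible(NULL)
}
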