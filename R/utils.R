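# Save the global RNG state, set a seed, and allow exact restoration, so
# package internals are reproducible without clobbering the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Chromosome labels are matched after stripping a leading "chr" and case
# folding, so "chr20", "Chr20" and "20" are the same chromosome.
normalize_chrom <- function(chrom) {
  sub("^chr", "", tolower(as.character(chrom)))
}

# Derive a per-response seed from a global seed and a response id so that
# results do not depend on execution order.  Kept below 2^31 - 1.
derive_seed <- function(seed, id) {
  h <- sum(utf8ToInt(as.character(id)) * (seq_along(utf8ToInt(as.character(id))) %% 97 + 1))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}
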