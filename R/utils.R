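# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic stage routes through this so a single pipeline seed
# gives byte-identical reruns.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a stage-specific seed from a global one, staying within the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Read a "#"-commented TSV into a character matrix of fields, keeping the
# originating line number of every row for error reporting.
read_tsv_fields <- function(path, min_fields, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: '%s'", what, path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    abort(sprintf("%s file '%s' contains no data lines.", what, path))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < min_fields)
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s file '%s': line %d has fewer than %d tab-separated fields.",
      what, path, keep[bad[1L]], min_fields
    ))
  }
  list(fields = fields, line_numbers = keep)
}

fmt_num <- function(x) sprintf("%.10g", x)
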