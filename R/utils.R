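# Shared internal helpers: label-set coercion, seed derivation, input checks.

# A label set collection is a list of non-empty character vectors, one per
# protein. Accept list columns, character vectors of ";"- or ","-separated
# names, or a single character vector (one protein).
as_label_sets <- function(x, allow_empty = FALSE) {
  if (is.character(x)) {
    x <- strsplit(x, "[;,]\\s*")
  }
  if (!is.list(x)) {
    abort("label sets must be a list of character vectors or a character vector")
  }
  x <- lapply(x, function(y) unique(as.character(y[!is.na(y) & nzchar(y)])))
  if (!allow_empty && any(lengths(x) == 0L)) {
    abort("every label set must be non-empty")
  }
  x
}

# Deterministic sub-seed so that all randomness flows from one user-visible
# seed. Kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(k)) %% 2147483647)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
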