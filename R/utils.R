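# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed; keeps values well inside 32-bit range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  # Double arithmetic: exact well past 2^31, result folded into integer range.
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Centered moving average; width forced odd; edges use shrinking windows so the
# series keeps its length and no NA padding leaks into correlations.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
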