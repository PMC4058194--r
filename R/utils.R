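`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL means "use the RNG stream as-is" (no reseeding).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
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

# Deterministic child seed for stream i, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483646L + 1)
}

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_f("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop_f("`%s` must be a single number in %s%g, %g%s", name,
           if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]")
  }
  as.numeric(x)
}
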