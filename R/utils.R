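# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a run seed; keeps results deterministic per stage
# while giving each stage an independent stream. Stays below 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  # double arithmetic is exact here (< 2^53) and avoids integer overflow;
  # the result stays below 2^31 for set.seed()
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483647)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
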