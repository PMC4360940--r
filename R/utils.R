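# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic entry points funnel through this so that a run
# is reproducible from its seed arguments alone.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derived sub-seeds stay inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1009 * as.double(offset)) %% 2147483646L) + 1L
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
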