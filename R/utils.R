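# Shared internal helpers.

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a 32-bit child seed from a root seed and a counter, so that
# independent units of work (cells, replicates, restarts) get their own
# reproducible stream regardless of evaluation order.
derive_seed <- function(root, counter) {
  s <- (as.double(root) %% 2147483629) * 48271 + as.double(counter) * 9973 + 1
  as.integer(s %% 2147483629) + 1L
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
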