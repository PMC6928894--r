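## Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seed without touching the caller's
# .Random.seed (no global state leaks; every stochastic op takes a seed).
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically expand one master seed into n per-unit seeds (< 2^31).
derive_seeds <- function(master_seed, n) {
  with_local_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Split indices 1..n into maximal runs where `new_run[i]` is TRUE at run starts.
run_ids <- function(new_run) {
  cumsum(as.integer(new_run))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
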