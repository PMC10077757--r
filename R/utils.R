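# Internal helpers shared across modules.

# Clamp to [lo, hi]; NA passes through.
clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Draw a child seed from the current RNG stream; always < 2^31.
child_seed <- function() sample.int(.Machine$integer.max, 1L)

# Evaluate `expr` with a local RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
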