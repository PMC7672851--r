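# internal helpers shared across the package

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators do not disturb user simulations.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Canonical unordered-pair key; "\r" cannot occur in whitespace-split ids.
pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
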