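# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from (seed, tag); kept within 32-bit integer range.
derive_seed <- function(seed, tag) {
  (as.numeric(seed) * 1000003 + as.numeric(tag) * 7919) %% 2147483647
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

rgumbel <- function(n) -log(-log(stats::runif(n)))
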