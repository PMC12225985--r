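# Seed plumbing: evaluate an expression under a temporary RNG state, and
# derive stable per-case sub-seeds from one master seed (all < 2^31).

with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
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

derive_seed <- function(master_seed, index, salt = 0) {
  m <- 2147483629
  s <- (as.numeric(master_seed) %% m)
  s <- (s * 48271 + as.numeric(salt) * 9973 + as.numeric(index)) %% m
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
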