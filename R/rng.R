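# Seed handling: every stochastic entry point takes an explicit integer seed
# and evaluates under a local RNG state, leaving .Random.seed untouched.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Documented splitting rule: stream k of root seed s is
# (s * 48271 + k * 7919) mod (2^31 - 1), kept strictly below 2^31.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k) * 7919
  as.integer(s %% 2147483647)
}
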