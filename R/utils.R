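# Internal helpers.

# An isolated RNG stream: draws do not disturb (and are not disturbed by)
# the global .Random.seed, so every simulator/sampler is independently
# reproducible from its own seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = genv)
  if (is.null(old)) rm(".Random.seed", envir = genv)
  else assign(".Random.seed", old, envir = genv)
  wrap <- function(f) {
    force(f)
    function(...) {
      prev <- get0(".Random.seed", envir = genv, inherits = FALSE)
      assign(".Random.seed", env$state, envir = genv)
      on.exit({
        env$state <- get(".Random.seed", envir = genv)
        if (is.null(prev)) rm(".Random.seed", envir = genv)
        else assign(".Random.seed", prev, envir = genv)
      })
      f(...)
    }
  }
  list(runif = wrap(stats::runif), rnorm = wrap(stats::rnorm),
       sample = wrap(base::sample), rbinom = wrap(stats::rbinom),
       sample_int = wrap(base::sample.int))
}

# Derive a sub-seed from a master seed and a stream index; stays within
# the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 65537) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
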