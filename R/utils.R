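# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards, so seeded helpers do not
# perturb an enclosing simulation.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Deterministic per-unit seed streams derived from one master seed.
# Counter-based so the result does not depend on generation order.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
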