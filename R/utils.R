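# Seeding helpers: every stochastic operation routes its randomness through
# with_seed() so the global RNG state is left untouched.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# (or removing) the caller's .Random.seed afterwards.
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
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Stages of the pipeline draw from independent streams derived
#' deterministically from one master seed: stage i gets
#' `(master + 1000003 * i) mod (2^31 - 1)`. The stage order is fixed and
#' documented in [default_run_config()].
#'
#' @param master integer master seed.
#' @param stage_index 1-based stage index.
#' @return integer seed.
#' @export
derive_stage_seed <- function(master, stage_index) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(stage_index)) %%
               (2^31 - 1))
}

# Marker used where a quantity is undefined (empty denominator, single
# observation, single-class replicate): plain NA_real_, with helper for
# readable checks.
undefined_value <- function() NA_real_
is_undefined <- function(x) is.na(x)
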