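# Deterministic seed substreams.
#
# Every stochastic component of a simulation draws from its own substream,
# derived from a single root seed and a (env, component, trait, extra) tuple.
# This keeps realisations stable under extension: adding a trait, or asking
# for an extra component, never perturbs the draws of the others.

# component codes used across the package
.COMP <- c(
  knot_pos  = 1L,
  knot_z    = 2L,
  ar1       = 3L,
  random    = 4L,
  ext_col   = 5L,
  ext_row   = 6L,
  ext_order = 7L,
  rcbd      = 8L,
  gv        = 9L
)

# Injective map (env, comp, trait, extra) -> seed, modulo the Mersenne prime
# 2^31 - 1. Valid for env < 8000, comp < 16, trait < 256, extra < 32; the
# multipliers are the classic Lehmer constants.
.substream_seed <- function(seed, env = 0L, comp = 0L, trait = 0L, extra = 0L) {
  stopifnot(env < 8000, comp < 16, trait < 256, extra < 32)
  idx <- ((as.double(env) * 16 + comp) * 256 + trait) * 32 + extra
  as.integer((as.double(seed %% 2147483647L) * 48271 + idx * 16807) %% 2147483647)
}

# Evaluate `code` under a given seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Resolve a user-supplied seed: NULL means "draw one from the session RNG",
# which keeps set.seed() at the top of a user script effective.
.resolve_seed <- function(seed) {
  if (is.null(seed)) {
    sample.int(2147483646L, 1L)
  } else {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, !is.na(seed))
    seed
  }
}
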