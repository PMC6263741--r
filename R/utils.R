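# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so generators never perturb user simulations.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# rows/cols validation for a (rows, cols) size argument
check_size <- function(size) {
  if (!is.numeric(size) || length(size) != 2L || any(size < 1) || any(size != round(size)))
    stop("`size` must be two positive integers (rows, cols)", call. = FALSE)
  as.integer(size)
}

# rescale a matrix linearly onto [lo, hi]; constant input maps to lo
rescale01 <- function(m, lo = 0, hi = 1) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(matrix(lo, nrow(m), ncol(m)))
  lo + (hi - lo) * (m - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
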