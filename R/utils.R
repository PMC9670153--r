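# Internal helpers: seeded RNG scoping and seed derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. Keeps every stochastic
# component reproducible without clobbering the user's session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Splitmix-style derivation of sub-seeds from a master seed plus a
# sequence of tags (integers or strings). Every stream of randomness in
# the package (database geometry, splits, FC init, batch order, dropout)
# draws its seed through this single documented hash, so one master seed
# determines the whole experiment. Arithmetic stays in doubles below
# 2^53, reduced mod (2^31 - 1) so the result is a valid R integer seed.
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- (as.numeric(master) %% m)
  for (tag in list(...)) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    for (t in as.numeric(tag)) {
      h <- (h * 69069 + t * 2654435.0 + 12345) %% m
      h <- (h * 3876.0 + 511) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
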