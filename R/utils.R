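# Internal helpers: interval counting, seed derivation, local RNG scope.

# Number of elements of sorted vector x in [a, b). Tolerance-free: spike
# times are doubles; half-open convention handled by findInterval on the
# closed-left side.
countInInterval <- function(x, a, b) {
  findInterval(b, x, left.open = TRUE) - findInterval(a, x, left.open = TRUE)
}

# Indices of sorted x falling in [a, b); returns integer(0) when empty.
whichInInterval <- function(x, a, b) {
  lo <- findInterval(a, x, left.open = TRUE) + 1L
  hi <- findInterval(b, x, left.open = TRUE)
  if (hi < lo) integer(0) else lo:hi
}

# Deterministic substream seed derivation: fold extra integer keys into the
# master seed with a multiplicative mix modulo 2^31 - 1. Order-dependent in
# its arguments, independent of call order elsewhere, always in [1, 2^31-2].
mixSeed <- function(seed, ...) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  for (k in c(...)) {
    s <- (s * 69069 + (as.numeric(k) + 1) * 40503) %% m
  }
  as.integer(s + 1)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Round to the 10-ms behavioral acquisition grid, with a floor of one tick.
snapToGrid <- function(x, grid = 10) pmax(grid, round(x / grid) * grid)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
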