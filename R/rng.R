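# Counter-style reproducible RNG used for all stochastic choices inside the
# forest builder (bootstrap draws, per-node feature subsets). A Lehmer
# (minimal standard, MINSTD) generator is used because its 31-bit state fits
# exactly in a double on every platform, so (seed, tree, node-path) streams
# are bit-reproducible regardless of R's global RNG kind, and independent
# streams can be derived by folding identifiers into the state.

.rng_m <- 2147483647  # 2^31 - 1, Mersenne prime modulus

# One Lehmer step via Schrage's decomposition (no intermediate overflow).
rng_next <- function(state) {
  hi <- state %/% 127773
  lo <- state %% 127773
  t <- 16807 * lo - 2836 * hi
  if (t <= 0) t + .rng_m else t
}

# Fold an arbitrary mix of numbers and strings into a valid Lehmer state in
# [1, m-1]. Used to key independent substreams, e.g. rng_fold(seed, tree_id)
# or rng_fold(tree_seed, "LRRL").
rng_fold <- function(...) {
  vals <- unlist(lapply(list(...), function(v) {
    if (is.character(v)) utf8ToInt(paste(v, collapse = "\x1f")) else as.numeric(v)
  }), use.names = FALSE)
  s <- 1299709  # arbitrary fixed prime starting state
  for (v in vals) {
    s <- rng_next(((s + (v %% (.rng_m - 1))) %% (.rng_m - 1)) + 1)
  }
  rng_next(s)
}

# k distinct values from 1..n via partial Fisher-Yates; returns the advanced
# state so callers can continue the stream.
rng_sample_distinct <- function(state, n, k) {
  stopifnot(k <= n)
  pool <- seq_len(n)
  for (i in seq_len(k)) {
    state <- rng_next(state)
    j <- i + (state - 1) %% (n - i + 1L)
    tmp <- pool[i]; pool[i] <- pool[j]; pool[j] <- tmp
  }
  list(state = state, values = pool[seq_len(k)])
}

# n draws with replacement from 1..n (a bootstrap resample).
rng_draws_with_replacement <- function(state, n, k = n) {
  out <- integer(k)
  for (i in seq_len(k)) {
    state <- rng_next(state)
    out[i] <- (state - 1) %% n + 1L
  }
  list(state = state, values = out)
}

# Run an expression under a fixed R RNG seed without disturbing the caller's
# RNG state (used by the synthetic-data generator).
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
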