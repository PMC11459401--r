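# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps all package randomness local to the
# seeds the user passes in.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1009 + (as.numeric(p) %% 1e6) + 7) %% 2147483629
  as.integer(h) + 1L
}

# Stratified fold assignment: within each class, rows are shuffled and dealt
# round-robin, so per-fold class counts differ by at most one. Relies on the
# caller having seeded the RNG.
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  offset <- 0L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}
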