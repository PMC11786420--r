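# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# one-hot matrix (n x k) from an integer class vector in 1..k
oneHot <- function(y, k) {
  out <- matrix(0, length(y), k)
  out[cbind(seq_along(y), y)] <- 1
  out
}

# Row-wise softmax with the usual max-shift for numerical stability.
rowSoftmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}
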