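# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a base seed and a stream offset.
# Keeps results inside the 32-bit integer range R's RNG accepts.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647L)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax of a numeric matrix. Row maxima via max.col (C speed).
softmax_rows <- function(z) {
  n <- nrow(z)
  mx <- z[cbind(seq_len(n), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / .rowSums(e, n, ncol(z))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# md5 of an arbitrary R object via base serialization (version 2 for
# cross-session stability).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}

# Broadcast a length-d vector across the rows of an n x d matrix.
row_broadcast <- function(v, n) {
  matrix(v, nrow = n, ncol = length(v), byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
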