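# Shared internal helpers.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise maximum without apply() overhead.
row_max <- function(m) {
  r <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2:ncol(m)) r <- pmax(r, m[, j])
  r
}

# Row-wise softmax of a matrix.
softmax_rows <- function(x) {
  e <- exp(x - row_max(x))
  e / rowSums(e)
}

# log of a multivariate normal density with full covariance (Cholesky based).
dmvnorm_log <- function(x, mean, sigma) {
  ch <- chol(sigma)
  d <- length(x)
  w <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(w * w)
}

is_diag_matrix <- function(m, tol = 0) {
  all(abs(m[row(m) != col(m)]) <= tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Slice class k out of a T x K x D array as a T x D matrix (dimension-safe).
slice3 <- function(arr, k) matrix(arr[, k, ], dim(arr)[1L], dim(arr)[3L])
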