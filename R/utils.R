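# internal helpers shared across modules

stop2 <- function(...) stop(..., call. = FALSE)

is_scalar_int <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

# row-wise log-sum-exp of a numeric matrix (column-wise pmax avoids apply())
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# one draw of `n` rows from a symmetric Dirichlet(alpha) of dimension k
rdirichlet <- function(n, k, alpha = 1) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n)
  g / rowSums(g)
}

# clamp probabilities to [floor, 1] and renormalize rows of a matrix
clamp_rows <- function(m, floor) {
  m <- pmax(m, floor)
  m / rowSums(m)
}

clamp_vec <- function(v, floor) {
  v <- pmax(v, floor)
  v / sum(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
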