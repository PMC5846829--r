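# Independent brute-force oracles, kept deliberately naive and separate from
# the package's vectorized implementations.

naive_simes <- function(p) {
  m <- length(p)
  ps <- sort(p)
  best <- Inf
  for (j in 1:m) best <- min(best, min(1, (m / j) * ps[j]))
  best
}

naive_meff <- function(R) {
  m <- nrow(R)
  if (m == 1) return(1)
  lam <- eigen(R, symmetric = TRUE)$values
  vl <- sum((lam - mean(lam))^2) / (m - 1)
  1 + (m - 1) * (1 - vl / m)
}

# TATES via explicit loops: eigendecompose the j x j submatrix of the
# p-value correlation matrix for each j along the sort order.
naive_tates <- function(p, R_p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  mej <- numeric(m)
  for (j in 1:m) {
    sub <- R_p[o[1:j], o[1:j], drop = FALSE]
    lam <- eigen(sub, symmetric = TRUE)$values
    excess <- 0
    for (l in lam) if (l > 1) excess <- excess + (l - 1)
    mej[j] <- j - excess
  }
  best <- Inf
  for (j in 1:m) best <- min(best, min(1, (mej[m] / mej[j]) * ps[j]))
  best
}

# Random positive-definite correlation matrix.
random_corr <- function(m) {
  A <- matrix(rnorm(m * m), m)
  S <- crossprod(A) + diag(m) * 0.5
  stats::cov2cor(S)
}
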