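# Input validation shared across the package.  Correlation matrices must be
# symmetric (1e-10), unit-diagonal, with eigenvalues >= -1e-8; p-value vectors
# must be complete probabilities.

.SYM_TOL <- 1e-10
.PSD_TOL <- 1e-8

check_pvalues <- function(p) {
  if (length(p) == 0L) stop("no p-values", call. = FALSE)
  if (!is.numeric(p)) stop("p-values must be numeric", call. = FALSE)
  if (anyNA(p)) stop("p-values contain missing entries", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  as.numeric(p)
}

check_corr <- function(R) {
  if (!is.matrix(R) || !is.numeric(R)) {
    stop("invalid correlation matrix: not a numeric matrix", call. = FALSE)
  }
  m <- nrow(R)
  if (ncol(R) != m) stop("invalid correlation matrix: not square", call. = FALSE)
  if (anyNA(R)) stop("invalid correlation matrix: missing entries", call. = FALSE)
  if (max(abs(R - t(R))) > .SYM_TOL) {
    stop("invalid correlation matrix: not symmetric", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > .SYM_TOL) {
    stop("invalid correlation matrix: diagonal not 1", call. = FALSE)
  }
  if (any(abs(R) > 1 + .SYM_TOL)) {
    stop("invalid correlation matrix: entries outside [-1, 1]", call. = FALSE)
  }
  if (m > 1L) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -.PSD_TOL) {
      stop("invalid correlation matrix: not positive semi-definite", call. = FALSE)
    }
  }
  R
}

# Eigenvalues of a symmetric PSD matrix, clipped at zero (tolerated noise
# down to -1e-8), sorted descending.
corr_eigenvalues <- function(R) {
  if (nrow(R) == 1L) return(1)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -.PSD_TOL) {
    stop("invalid correlation matrix: not positive semi-definite", call. = FALSE)
  }
  sort(pmax(ev, 0), decreasing = TRUE)
}

is_compound_symmetric <- function(R, tol = 1e-12) {
  m <- nrow(R)
  if (m < 2L) return(TRUE)
  off <- R[upper.tri(R)]
  max(abs(off - off[1L])) <= tol
}
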