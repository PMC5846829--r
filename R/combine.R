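#' Sort p-values ascendingly with a stable permutation
#'
#' Sorts a vector of per-phenotype p-values in nondecreasing order and returns
#' the permutation mapping sorted positions back to the original phenotype
#' indices. Ties are broken by original index (stable sort), so the ordering
#' of tied p-values is reproducible.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, length `m >= 1`, no
#'   missing values.
#' @return A list with elements `sorted` (nondecreasing numeric vector) and
#'   `order` (integer permutation: `sorted[j] == p[order[j]]`).
#' @examples
#' sort_ascending(c(0.04, 0.01, 0.9))
#' @export
sort_ascending <- function(p) {
  p <- check_pvalues(p)
  o <- order(p)  # radix/stable: ties keep original index order
  list(sorted = p[o], order = o)
}

comb_result <- function(method, combined_p, selected_rank, order, weights,
                        effective_counts = NULL) {
  structure(
    list(method = method,
         combined_p = combined_p,
         selected_rank = selected_rank,
         selected_trait = order[selected_rank],
         weights = weights,
         effective_counts = effective_counts),
    class = "comb_test")
}

#' @export
print.comb_test <- function(x, ...) {
  cat(sprintf("%s combination test\n", x$method))
  cat(sprintf("  combined p-value: %.6g\n", x$combined_p))
  cat(sprintf("  selected rank: %d (trait %d of %d)\n",
              x$selected_rank, x$selected_trait, length(x$weights)))
  invisible(x)
}

#' Simes combination test
#'
#' Sorts the `m` p-values ascendingly, weights the `j`th sorted p-value by
#' `m/j`, and returns the smallest weighted p-value (capped at 1). The
#' smallest p-value thus receives the largest weight (`m`) and the largest
#' p-value weight 1.
#'
#' @inheritParams sort_ascending
#' @return An object of class `"comb_test"` with elements `method`,
#'   `combined_p`, `selected_rank` (rank `j` of the selected sorted p-value),
#'   `selected_trait`, and `weights`.
#' @examples
#' simes_test(c(0.01, 0.04, 0.9))$combined_p  # min(3*0.01, 1.5*0.04, 0.9)
#' @export
simes_test <- function(p) {
  s <- sort_ascending(p)
  m <- length(s$sorted)
  w <- m / seq_len(m)
  weighted <- pmin(1, w * s$sorted)
  j <- which.min(weighted)
  comb_result("simes", weighted[j], j, s$order, w)
}

#' Bonferroni minP combination test
#'
#' Weights every p-value by `m` (Bonferroni correction) and selects the
#' smallest, i.e. `min(1, m * min(p))`.
#'
#' @inheritParams sort_ascending
#' @return A `"comb_test"` object; `selected_rank` is always 1.
#' @examples
#' minp_bonf(c(0.01, 0.04))$combined_p  # 0.02
#' @export
minp_bonf <- function(p) {
  s <- sort_ascending(p)
  m <- length(s$sorted)
  comb_result("minp_bonf", min(1, m * s$sorted[1L]), 1L, s$order, rep(m, m))
}

#' Effective number of independent phenotypes (Nyholt)
#'
#' Computes `M_eff = 1 + (m - 1) * (1 - Var(lambda) / m)` from the eigenvalue
#' spectrum `lambda` of an `m x m` phenotypic correlation matrix, with the
#' sample variance using denominator `m - 1`. `M_eff` equals `m` for the
#' identity matrix (no redundancy) and shrinks towards 1 as the phenotypes
#' become collinear (a rank-one correlation matrix gives exactly 1).
#'
#' @param R Symmetric positive semi-definite correlation matrix with unit
#'   diagonal.
#' @return A scalar in `[1, m]`.
#' @examples
#' nyholt_meff(diag(4))                              # 4
#' nyholt_meff(matrix(c(1, .5, .5, 1), 2))           # 1.75
#' @export
nyholt_meff <- function(R) {
  R <- check_corr(R)
  m <- nrow(R)
  if (m == 1L) return(1)
  lambda <- corr_eigenvalues(R)
  1 + (m - 1) * (1 - stats::var(lambda) / m)
}

#' Effective-number-of-tests minP combination test
#'
#' Like [minp_bonf()] but corrects the minimal p-value by the effective
#' number of phenotypes `M_eff` ([nyholt_meff()]) of the phenotypic
#' correlation matrix rather than by the observed number `m`. Because
#' `M_eff <= m`, this test is never stricter than Bonferroni minP. Two
#' correction styles are offered: multiplicative (`min(1, M_eff * min p)`,
#' the default) and Sidak (`1 - (1 - min p)^M_eff`); the two are numerically
#' close for small p-values.
#'
#' @inheritParams sort_ascending
#' @param R Phenotypic correlation matrix (`m x m`) matching `length(p)`.
#' @param style `"multiplicative"` or `"sidak"`.
#' @return A `"comb_test"` object; `effective_counts` holds `M_eff`.
#' @examples
#' minp_ns(c(0.02, 0.5), matrix(c(1, .5, .5, 1), 2))$combined_p  # 1.75 * 0.02
#' @export
minp_ns <- function(p, R, style = c("multiplicative", "sidak")) {
  style <- match.arg(style)
  s <- sort_ascending(p)
  m <- length(s$sorted)
  R <- check_corr(R)
  if (nrow(R) != m) stop("dimension mismatch between p-values and correlation matrix",
                         call. = FALSE)
  meff <- nyholt_meff(R)
  pmin1 <- s$sorted[1L]
  combined <- if (style == "multiplicative") min(1, meff * pmin1)
              else 1 - (1 - pmin1)^meff
  comb_result("minp_ns", combined, 1L, s$order, rep(meff, m),
              effective_counts = meff)
}

#' Effective numbers of p-values for TATES weighting
#'
#' For each `j = 1..m` computes
#' `m_ej = j - sum_i I(lambda_i > 1) * (lambda_i - 1)`, where `lambda_i` are
#' the eigenvalues of the `j x j` leading submatrix of the p-value
#' correlation matrix after reordering rows and columns by `perm` (phenotypes
#' ordered by ascending p-value). `m_e = m_em` is the effective number over
#' all `m` p-values.
#'
#' `m_ej` is not guaranteed to be nondecreasing in `j`; it always satisfies
#' `0 < m_ej <= j`.
#'
#' @param R_p Correlation matrix among the p-values (see
#'   [pval_correlation_map()]).
#' @param perm Integer permutation of `1:m` ordering phenotypes by ascending
#'   p-value; defaults to the identity.
#' @return Numeric vector `c(m_e1, ..., m_em)`.
#' @examples
#' tates_effective_counts(diag(3))                       # 1 2 3
#' tates_effective_counts(matrix(c(1, .5, .5, 1), 2))    # 1 1.5
#' @export
tates_effective_counts <- function(R_p, perm = seq_len(nrow(R_p))) {
  R_p <- check_corr(R_p)
  m <- nrow(R_p)
  if (length(perm) != m || !setequal(perm, seq_len(m))) {
    stop("perm must be a permutation of 1:m", call. = FALSE)
  }
  Rr <- R_p[perm, perm, drop = FALSE]
  vapply(seq_len(m), function(j) {
    lambda <- corr_eigenvalues(Rr[seq_len(j), seq_len(j), drop = FALSE])
    mej <- j - sum((lambda - 1)[lambda > 1])
    if (mej <= 0) stop("degenerate effective count m_ej <= 0", call. = FALSE)
    mej
  }, numeric(1))
}

#' TATES combination test
#'
#' The trait-based association test using extended Simes. The `m` univariate
#' p-values are sorted ascendingly and the `j`th sorted p-value is weighted
#' by `m_e / m_ej`, where the effective numbers `m_ej` come from the
#' eigenvalues of the correlation matrix among the `j` smallest p-values
#' ([tates_effective_counts()]). The combined p-value is the smallest
#' weighted p-value (capped at 1). All weights are `>= 1` and the largest
#' sorted p-value receives weight exactly 1, so under an identity correlation
#' matrix TATES coincides with [simes_test()].
#'
#' The correlation matrix among p-values is obtained from the phenotypic
#' correlation matrix via [pval_correlation_map()]; the default `"pnorm"` map
#' is the exact correlation of two-sided normal-score p-values.
#'
#' @inheritParams sort_ascending
#' @param R_pheno Phenotypic correlation matrix (`m x m`).
#' @param map Name of a registered p-value correlation map, or a function
#'   `f(rho)`; see [pval_correlation_map()].
#' @return A `"comb_test"` object; `effective_counts` holds `m_e1..m_em`.
#' @examples
#' tates(c(0.01, 0.04, 0.9), diag(3))$combined_p  # Simes: 0.03
#' @export
tates <- function(p, R_pheno, map = "pnorm") {
  s <- sort_ascending(p)
  m <- length(s$sorted)
  R_pheno <- check_corr(R_pheno)
  if (nrow(R_pheno) != m) stop("dimension mismatch between p-values and correlation matrix",
                               call. = FALSE)
  R_p <- pval_correlation_map(R_pheno, map)
  mej <- tates_effective_counts(R_p, s$order)
  w <- mej[m] / mej
  weighted <- pmin(1, w * s$sorted)
  j <- which.min(weighted)
  comb_result("tates", weighted[j], j, s$order, w, effective_counts = mej)
}
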