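# Mapping phenotypic correlations to correlations among univariate p-values.
#
# TATES weights depend on the correlation matrix of the m p-values, which is
# approximated from the phenotypic correlations.  For two standard normal
# test statistics with correlation rho, the two-sided p-values
# p_i = 2*pnorm(-|Z_i|) are Uniform(0,1) marginally with Var = 1/12, so
#   cor(p_1, p_2) = 12 * (E[p_1 p_2] - 1/4).
# The expectation is computed by nested adaptive quadrature; the inner
# integrand has a kink where rho*z + sqrt(1-rho^2)*u = 0, so the inner
# integral is split there.  f is even in rho, f(0) = 0, f(1) = 1.

.pval_maps <- new.env(parent = emptyenv())
.pval_cor_cache <- new.env(parent = emptyenv())

# Exact cor(p1, p2) for bivariate-normal scores with correlation rho.
pval_cor_pnorm <- function(rho) {
  rho <- abs(rho)
  if (rho >= 1 - 1e-12) return(1)
  if (rho < 1e-12) return(0)
  key <- sprintf("%.15g", rho)
  hit <- .pval_cor_cache[[key]]
  if (!is.null(hit)) return(hit)
  b <- sqrt(1 - rho^2)
  inner <- function(z) {
    u0 <- -rho * z / b
    g <- function(u) stats::dnorm(u) * 2 * stats::pnorm(-abs(rho * z + b * u))
    stats::integrate(g, -Inf, u0, rel.tol = 1e-10)$value +
      stats::integrate(g, u0, Inf, rel.tol = 1e-10)$value
  }
  outer_fn <- function(zv) {
    vapply(zv, function(z) stats::dnorm(z) * 2 * stats::pnorm(-z) * inner(z),
           numeric(1))
  }
  E <- 2 * stats::integrate(outer_fn, 0, Inf, rel.tol = 1e-9)$value
  val <- min(1, max(0, 12 * (E - 0.25)))
  assign(key, val, envir = .pval_cor_cache)
  val
}

#' Register a p-value correlation map
#'
#' Adds a named scalar map `f(rho)` translating a phenotypic correlation into
#' the implied correlation between the two univariate p-values. Registered
#' maps can be selected by name in [pval_correlation_map()] and [tates()].
#' The built-in maps are `"pnorm"` (exact two-sided normal-score p-value
#' correlation, the default used by TATES) and `"identity"` (use the
#' phenotypic correlations unchanged).
#'
#' @param name Character name for the map.
#' @param fn Function of one numeric scalar returning a correlation in
#'   `[-1, 1]`; must satisfy `fn(0) == 0` and `fn(1) == 1`.
#' @return Invisibly, `name`.
#' @export
register_pval_map <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .pval_maps)
  invisible(name)
}

#' Approximate the correlation matrix among univariate p-values
#'
#' Applies a scalar correlation map entrywise to the off-diagonal elements of
#' a phenotypic correlation matrix, yielding the approximated correlation
#' matrix among the `m` univariate p-values used by TATES. The default
#' `"pnorm"` map is the exact correlation between two-sided p-values of
#' bivariate standard-normal test statistics, computed by numerical
#' quadrature (and cached per correlation value); `"identity"` passes the
#' phenotypic correlations through unchanged. Both maps fix 0 and 1, so an
#' identity input matrix maps to itself.
#'
#' @param R_pheno Phenotypic correlation matrix.
#' @param map Registered map name (see [register_pval_map()]) or a function.
#' @return A valid correlation matrix of the same dimension.
#' @examples
#' pval_correlation_map(diag(3))                        # identity in, identity out
#' pval_correlation_map(matrix(c(1, .9, .9, 1), 2))[1, 2]
#' @export
pval_correlation_map <- function(R_pheno, map = "pnorm") {
  R_pheno <- check_corr(R_pheno)
  fn <- if (is.function(map)) {
    map
  } else {
    got <- get0(map, envir = .pval_maps, inherits = FALSE)
    if (is.null(got)) stop(sprintf("unknown p-value correlation map '%s'", map),
                           call. = FALSE)
    got
  }
  m <- nrow(R_pheno)
  R_p <- diag(m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        v <- fn(R_pheno[i, j])
        R_p[i, j] <- v
        R_p[j, i] <- v
      }
    }
  }
  dimnames(R_p) <- dimnames(R_pheno)
  check_corr(R_p)
}

assign("pnorm", pval_cor_pnorm, envir = .pval_maps)
assign("identity", function(rho) rho, envir = .pval_maps)
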