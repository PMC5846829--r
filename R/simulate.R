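#' Compound-symmetric correlation matrix
#'
#' Builds the `m x m` correlation matrix with unit diagonal and all
#' off-diagonal entries equal to `r` (all phenotypes equally correlated,
#' consistent with a single parallel factor model). Positive
#' semi-definiteness requires `r > -1/(m-1)`.
#'
#' @param m Number of phenotypes (`>= 1`).
#' @param r Common correlation.
#' @return A valid correlation matrix.
#' @examples
#' compound_symmetric(2, 0.9)
#' @export
compound_symmetric <- function(m, r) {
  stopifnot(length(m) == 1L, m >= 1, m == as.integer(m), length(r) == 1L)
  if (m > 1L && (r > 1 || r <= -1 / (m - 1))) {
    stop(sprintf("r = %g outside the positive semi-definite range (-1/(m-1), 1]", r),
         call. = FALSE)
  }
  R <- matrix(r, m, m)
  diag(R) <- 1
  check_corr(R)
}

#' Three-phenotype replication correlation matrix
#'
#' The 3x3 phenotypic correlation matrix with pairwise correlations
#' `r12 = 0.81`, `r13 = 0.95`, `r23 = 0.78`, used as a high-correlation
#' replication scenario for empirical Type I error estimation.
#'
#' @return A valid 3x3 correlation matrix.
#' @export
aliev_matrix <- function() {
  R <- matrix(c(1, 0.81, 0.95,
                0.81, 1, 0.78,
                0.95, 0.78, 1), 3, 3, byrow = TRUE)
  check_corr(R)
}

#' Simulate diallelic genotypes under Hardy-Weinberg equilibrium
#'
#' Draws `n` allele counts in `{0, 1, 2}` i.i.d. from the Hardy-Weinberg
#' genotype distribution for a diallelic variant with minor allele frequency
#' `maf`, i.e. Binomial(2, maf). Uses the session RNG.
#'
#' @param n Number of subjects.
#' @param maf Minor allele frequency, in `(0, 0.5]`.
#' @return Integer vector of allele counts.
#' @export
simulate_genotypes <- function(n, maf) {
  stopifnot(length(n) == 1L, n >= 1)
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  stats::rbinom(n, 2L, maf)
}

# Factor L with L %*% t(L) = R; Cholesky when positive definite, symmetric
# eigen square root for PSD-singular matrices (e.g. r = 1).
corr_factor <- function(R) {
  L <- tryCatch(t(chol(R)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R))
}

#' Simulate multivariate-normal phenotypes
#'
#' Draws `n` i.i.d. rows from a zero-mean multivariate normal distribution
#' with covariance equal to the given correlation matrix (unit variances).
#' Uses the session RNG.
#'
#' @param n Number of subjects.
#' @param R Phenotypic correlation matrix (`m x m`).
#' @return Numeric `n x m` matrix.
#' @export
simulate_phenotypes <- function(n, R) {
  stopifnot(length(n) == 1L, n >= 1)
  R <- check_corr(R)
  m <- nrow(R)
  Z <- matrix(stats::rnorm(n * m), n, m)
  Z %*% t(corr_factor(R))
}

#' Define a null-simulation scenario
#'
#' Bundles the parameters of one Monte-Carlo cell: number of phenotypes `m`,
#' their correlation structure (a single compound-symmetry correlation `r` or
#' a full matrix `corr`), sample size `n`, minor allele frequency `maf`,
#' number of simulation replicates `nsim`, nominal significance level
#' `alpha`, and RNG `seed`.
#'
#' @param m Number of phenotypes.
#' @param r Common correlation for a compound-symmetric structure (used when
#'   `corr` is `NULL`).
#' @param corr Optional full `m x m` correlation matrix (overrides `r`).
#' @param n Number of subjects per replicate.
#' @param maf Minor allele frequency of the simulated variant, `(0, 0.5]`.
#' @param nsim Number of simulation replicates.
#' @param alpha Nominal significance level, strictly in `(0, 1)`.
#' @param seed Integer RNG seed for the scenario.
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec(m = 2, r = 0.9, n = 2000, maf = 0.5, nsim = 1000, seed = 1)
#' @export
scenario_spec <- function(m, r = 0, corr = NULL, n = 2000, maf = 0.5,
                          nsim = 10000, alpha = 0.05, seed = 1) {
  stopifnot(length(m) == 1L, m >= 1, m == as.integer(m))
  if (is.null(corr)) corr <- compound_symmetric(m, r) else {
    corr <- check_corr(corr)
    if (nrow(corr) != m) stop("corr dimension does not match m", call. = FALSE)
    r <- NA_real_
  }
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  stopifnot(nsim >= 1, n >= 3, length(seed) == 1L)
  structure(
    list(m = as.integer(m), r = r, corr = corr, n = as.integer(n),
         maf = maf, nsim = as.integer(nsim), alpha = alpha,
         seed = as.integer(seed)),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  rtxt <- if (is.na(x$r)) "custom matrix" else sprintf("compound symmetric r = %g", x$r)
  cat(sprintf("Null-simulation scenario: m = %d phenotypes (%s)\n", x$m, rtxt))
  cat(sprintf("  N = %d, MAF = %g, Nsim = %d, alpha = %g, seed = %d\n",
              x$n, x$maf, x$nsim, x$alpha, x$seed))
  invisible(x)
}

#' Simulate one null dataset
#'
#' Generates genotypes and phenotypes for a single replicate of a scenario
#' under the null hypothesis of no association: the genotype vector and the
#' phenotype matrix are drawn independently. The scenario seed initialises
#' the RNG; the genotype stream is drawn first, then the phenotype stream,
#' so the draw order is reproducible.
#'
#' @param spec A [scenario_spec()].
#' @return A list of class `"null_dataset"` with `genotypes` (length-`n`
#'   integer vector of allele counts) and `phenotypes` (`n x m` matrix).
#' @export
simulate_null_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  g <- simulate_genotypes(spec$n, spec$maf)
  Y <- simulate_phenotypes(spec$n, spec$corr)
  colnames(Y) <- paste0("pheno_", seq_len(spec$m))
  structure(list(genotypes = g, phenotypes = Y, spec = spec),
            class = "null_dataset")
}

#' @export
print.null_dataset <- function(x, ...) {
  cat(sprintf("Null dataset: %d subjects, %d phenotypes, allele frequency %.3f\n",
              length(x$genotypes), ncol(x$phenotypes),
              mean(x$genotypes) / 2))
  invisible(x)
}
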