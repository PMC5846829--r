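#' Univariate SNP-phenotype association p-values
#'
#' Regresses each phenotype individually on the allele count (ordinary least
#' squares with intercept, no covariates) and returns the two-sided p-value
#' of the slope from the t distribution with `n - 2` degrees of freedom. All
#' `m` phenotypes are handled in one vectorized pass via the identity
#' `t = r * sqrt((n - 2) / (1 - r^2))`, where `r` is the genotype-phenotype
#' sample correlation; this is algebraically the OLS slope t-statistic, so
#' the p-values are invariant to affine rescaling of the phenotypes.
#'
#' @param data A `"null_dataset"` from [simulate_null_dataset()], or any list
#'   with `genotypes` (numeric vector) and `phenotypes` (matrix with one
#'   column per phenotype).
#' @return A list of class `"assoc_result"` with `pvalues` (length `m`),
#'   `tstats`, and `df` (`n - 2`).
#' @export
univariate_pvalues <- function(data) {
  g <- as.numeric(data$genotypes)
  Y <- as.matrix(data$phenotypes)
  n <- length(g)
  if (nrow(Y) != n) stop("genotype and phenotype dimensions differ", call. = FALSE)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  gc <- g - mean(g)
  sgg <- sum(gc^2)
  if (sgg == 0) stop("monomorphic variant", call. = FALSE)
  Yc <- sweep(Y, 2L, colMeans(Y))
  syy <- colSums(Yc^2)
  sgy <- as.numeric(crossprod(gc, Yc))
  r <- sgy / sqrt(sgg * syy)
  r <- pmin(1, pmax(-1, r))
  df <- n - 2L
  tstat <- ifelse(abs(r) >= 1, sign(r) * Inf, r * sqrt(df / (1 - r^2)))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(pvalues = unname(p), tstats = unname(tstat), df = df),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("Univariate association: %d phenotypes, df = %d\n",
              length(x$pvalues), x$df))
  cat("  p-values:", format(x$pvalues, digits = 4), "\n")
  invisible(x)
}
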