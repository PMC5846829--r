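Package: tatesim
Title: Weighted-Selection P-Value Combination Tests for Multivariate GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements four combination tests for assessing the association
    between a single genetic variant and multiple correlated phenotypes by
    weighted selection of the minimal univariate p-value: TATES (extended
    Simes with effective numbers of p-values derived from the eigenvalues of
    the p-value correlation matrix), the Simes test, Bonferroni minP, and
    Nyholt/Sidak effective-number minP. Includes a multivariate-normal null
    simulator (Hardy-Weinberg genotypes, compound-symmetric or arbitrary
    phenotypic correlation structures), per-phenotype ordinary least squares
    association p-values, and a Monte-Carlo framework for estimating
    empirical Type I error rates with binomial confidence intervals, grid
    summaries, and null p-value distribution diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
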