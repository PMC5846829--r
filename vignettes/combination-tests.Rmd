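---
title: "Weighted-selection combination tests and their Type I error under the null"
author: "tatesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-selection combination tests and their Type I error under the null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tatesim)
```

## The multivariate testing problem

In a univariate genome-wide association study a phenotype is regressed on the
allele count of a single nucleotide polymorphism (SNP), yielding one p-value.
With $m$ phenotypes one obtains $m$ univariate p-values
$p_1, \dots, p_m$ per SNP, and a *combination test* aggregates them into a
single test of the multivariate null hypothesis that none of the $m$
phenotypes is associated with the SNP. This package implements four
combination tests that all work by *weighted selection*: each p-value is
multiplied by a weight $\ge 1$ and the smallest weighted p-value is selected
as the combined p-value (capped at 1).

Writing $p_{(1)} \le \dots \le p_{(m)}$ for the sorted p-values:

* **minP$_\text{Bonf}$** — every p-value is weighted by $m$:
  $p_\text{comb} = \min(1, m\,p_{(1)})$.
* **minP$_\text{NS}$** — weight by the *effective* number of phenotypes
  $M_\text{eff}$ instead of $m$, where
  $M_\text{eff} = 1 + (m-1)\left(1 - \operatorname{Var}(\lambda)/m\right)$
  from the eigenvalues $\lambda$ of the $m \times m$ phenotypic correlation
  matrix (sample variance with denominator $m-1$). $M_\text{eff} \le m$
  always, so minP$_\text{NS}$ is never stricter than minP$_\text{Bonf}$.
* **Simes** — the $j$th sorted p-value is weighted by $m/j$:
  $p_\text{comb} = \min_j (m/j)\, p_{(j)}$.
* **TATES** — as Simes, but with $m$ and $j$ replaced by effective numbers:
  $p_\text{comb} = \min_j (m_e/m_{ej})\, p_{(j)}$, with
  $$ m_{ej} = j - \sum_{i=1}^{j} I(\lambda_i > 1)(\lambda_i - 1), $$
  where $\lambda_i$ are the eigenvalues of the correlation matrix among the
  $j$ *smallest* p-values (the leading $j \times j$ submatrix after sorting),
  and $m_e = m_{em}$. All weights $m_e/m_{ej}$ are $\ge 1$ and the largest
  sorted p-value always carries weight exactly 1, so under an identity
  correlation matrix TATES reduces exactly to Simes.

```{r}
p <- c(0.01, 0.04, 0.9)
simes_test(p)$combined_p
tates(p, diag(3))$combined_p       # identity correlation: equals Simes
minp_bonf(p)$combined_p
```

## From phenotypic correlations to p-value correlations

The TATES eigenvalues are those of the correlation matrix *among the
p-values*, which must be approximated from the phenotypic correlations. This
approximation matters. For two standard-normal test statistics with
correlation $\rho$, the two-sided p-values $p_i = 2\Phi(-|Z_i|)$ are each
Uniform(0,1), and their correlation is

$$ f(\rho) = 12\left( \mathbb{E}[p_1 p_2] - \tfrac14 \right), $$

an even function of $\rho$ with $f(0)=0$, $f(1)=1$, and $f(\rho) < |\rho|$
in between (e.g. $f(0.9) \approx 0.701$): taking absolute values discards the
signs of the statistics, so p-values are always less correlated than the
statistics themselves. `pval_correlation_map()` computes $f$ exactly by
nested adaptive quadrature (the inner integrand has a kink where the folded
statistic changes sign, so the inner integral is split there; results are
cached per correlation value). This `"pnorm"` map is the default for
`tates()`. Substituting the raw phenotypic correlations (`map = "identity"`)
systematically overstates the redundancy among p-values, shrinks $m_{e2}$,
inflates the weight on the smallest p-value, and drives the TATES Type I
error at $m=2, r=0.9$ from $\approx 0.055$ up to $\approx 0.064$ — which is
why the identity map is available but not the default. Custom maps (for
instance a fitted polynomial) can be supplied via `register_pval_map()`.

$M_\text{eff}$ for minP$_\text{NS}$, in contrast, is defined directly on the
phenotypic correlation matrix and uses no map.

```{r}
pval_correlation_map(compound_symmetric(2, 0.9))[1, 2]
nyholt_meff(compound_symmetric(2, 0.9))
```

## The null simulator

`scenario_spec()` describes one Monte-Carlo cell. Its defaults encode the
study conditions used throughout: $N = 2000$ subjects, a single unassociated
diallelic variant with MAF $= 0.5$, and $m$ phenotypes that are jointly
normal with zero means, unit variances, and a compound-symmetric correlation
matrix (all off-diagonals equal to $r$) — the structure implied by a single
parallel factor model. Phenotype normality is adopted because the univariate
test is an OLS t-test whose p-values are exactly uniform under normal errors;
the simulator does not emulate non-normal phenotypes, missing data,
covariates, case-control ascertainment, or factor/network covariance
structures, so passing tests here say nothing about robustness to those
features of real data. Genotypes are drawn as Binomial(2, MAF) — the
Hardy-Weinberg genotype distribution — and independently of the phenotypes,
which is exactly the null hypothesis.

The association step regresses each phenotype on the allele count (OLS with
intercept, two-sided t-test with $N-2$ degrees of freedom), vectorized over
phenotypes and replicates via the identity $t = r\sqrt{(N-2)/(1-r^2)}$ with
$r$ the genotype-phenotype sample correlation.

### Reproducibility mechanics

The Monte-Carlo engine processes replicates in batches whose size is a
deterministic function of $N$ and $m$ (about $4 \times 10^6$ phenotype draws
per batch, capping memory). Each batch draws its genotype stream and its
phenotype stream from separate seeds derived from the scenario seed and the
batch index, and phenotype draws are laid out contiguously per replicate.
Consequently results are bit-reproducible given the scenario spec, and
*extending* `nsim` leaves all earlier replicates unchanged — convenient when
refining a Monte-Carlo estimate.

Numerical choices: correlation matrices must be symmetric within $10^{-10}$
with eigenvalues $\ge -10^{-8}$ (small negative eigenvalues are clipped to
zero); singular structures such as $r = 1$ are factored by symmetric eigen
square root where Cholesky fails; tied p-values are sorted stably by
original phenotype index, which fixes the TATES submatrix ordering (the
combined value depends on tie order only through that submatrix); weighted
p-values above 1 are truncated to 1 before selection; rejection uses the
strict inequality $p_\text{comb} < \alpha$ (ties at $\alpha$ have
probability zero under this continuous model).

## Type I error experiments

`run_scenario()` estimates the empirical Type I error of all four tests for
one scenario; `run_grid()` aggregates a list of scenarios into per-method
summaries (mean, SD, largest overshoot above $\alpha$, largest undershoot
below $\alpha$, sum of absolute deviations). `table1_scenarios()` builds the
standard 20-cell grid crossing $m \in \{2,4,8,16\}$ with
$r \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$.

```{r, eval = FALSE}
grid <- run_grid(table1_scenarios(nsim = 10000, seed = 101), keep = 10000)
grid$grid
```

For a rejection proportion estimated from `nsim` replicates, `ci95()` gives
the normal-approximation interval
$p \pm 1.96\sqrt{p(1-p)/\textit{nsim}}$; each scenario rate is flagged
against the reference intervals at Nsim $= 10^5$ and $10^4$ (as in the
standard presentation of this grid) and against the interval at its own
`nsim`. The normal approximation is used, rather than an exact binomial
interval, because its endpoints are the conventional reference values
(0.04865-0.05135 at Nsim $= 10^5$).

With 10,000 replicates per cell the grid completes in a few minutes on one
CPU; the per-method *means* over 20 cells then carry a Monte-Carlo standard
error of about $5 \times 10^{-4}$, ample for the acceptance checks. The test
suite and the acceptance script both use this size; per-cell estimates at
this size have standard error $\approx 0.002$ at $\alpha = 0.05$.

`rates_at_alpha()` recounts rejections at a stricter $\alpha$ (0.01, 0.001)
from the retained combined p-values without re-simulating — the same
replicates, a different threshold.

## Null distributions of combined p-values

The univariate p-values feeding the combination tests are uniform under the
null, but the *selected minimum weighted* p-value is not, and is not expected
to be: uniformity of the output is not a correctness criterion for a
selection-based procedure, whose Type I error is controlled at the chosen
$\alpha$ thresholds rather than through distributional uniformity.
`pvalue_distribution()` makes the shapes visible: equal-weight selection
(minP$_\text{Bonf}$, minP$_\text{NS}$) produces a right-skewed distribution
(median above 0.5), while Simes and TATES — whose largest sorted p-value
keeps weight 1 — very often return that largest p-value and pile mass into
the top of the unit interval, increasingly so for larger $m$ and stronger
correlations. The function reports 20-bin histogram counts (bin count chosen
for display; the Kolmogorov-Smirnov distance is bin-free), KS distances from
Uniform(0,1), and medians.

## Design choices that were genuinely open

* **Effective-number formula for minP$_\text{NS}$**: the
  eigenvalue-variance form
  $M_\text{eff} = 1 + (m-1)(1-\operatorname{Var}(\lambda)/m)$ is used; it is
  the standard spectral effective-number-of-tests estimator, maps the
  identity to $m$ and rank-one matrices to 1, and reproduces the reference
  grid's minP$_\text{NS}$ column.
* **minP$_\text{NS}$ correction style**: multiplicative
  ($\min(1, M_\text{eff}\, p_{(1)})$) by default — the literal "smallest
  weighted p-value" — with the Šidák form $1-(1-p_{(1)})^{M_\text{eff}}$
  available (`style = "sidak"`). At these magnitudes the two differ by less
  than the Monte-Carlo noise of any feasible simulation, so the choice is
  presentational rather than substantive.
* **True versus estimated correlation matrix**: the simulation experiments
  feed the *generating* phenotypic correlation matrix to TATES and
  minP$_\text{NS}$. This isolates the behaviour of the combination rules
  from sampling noise in a correlation estimate; at $N = 2000$ the
  difference is negligible, and an applied analysis would substitute the
  sample correlation matrix.
* **Replication scenario parameters**: the three-phenotype high-correlation
  replication matrix (`aliev_matrix()`) is run at $N = 2000$, MAF $= 0.5$
  like the main grid; under the null the Type I error is insensitive to both
  asymptotically.

## Known limitations

Only the null (no association) is simulated: the package measures size, not
power. One SNP at a time; no gene-based aggregation over SNP sets, no
logistic models, no covariates, and no estimation of p-value correlations
from genome-wide empirical null SNPs. The `"pnorm"` correlation map assumes
the univariate statistics are (asymptotically) jointly normal with
correlation equal to the phenotypic correlation — correct for OLS on a shared
regressor under multivariate-normal phenotypes, an approximation elsewhere.
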