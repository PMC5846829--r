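#' Normal-approximation 95% confidence interval for a rejection rate
#'
#' For a nominal proportion `p` estimated from `nsim` Monte-Carlo
#' replicates, `SE = sqrt(p * (1 - p) / nsim)` and the interval is
#' `(p - 1.96 * SE, p + 1.96 * SE)`.
#'
#' @param p Proportion, strictly between 0 and 1.
#' @param nsim Number of replicates (`>= 1`).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' ci95(0.05, 100000)  # (0.04865, 0.05135)
#' ci95(0.05, 2000)    # approx (0.0404, 0.0596)
#' @export
ci95 <- function(p, nsim) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(nsim >= 1)
  se <- sqrt(p * (1 - p) / nsim)
  c(lower = p - 1.96 * se, upper = p + 1.96 * se)
}

# Table-1-style flag: outside the reference CI at Nsim = 1e5 ("italic"),
# outside the reference CI at Nsim = 1e4 ("italic bold"), or inside both.
reference_flag <- function(rate, alpha) {
  ci100k <- ci95(alpha, 1e5)
  ci10k <- ci95(alpha, 1e4)
  ifelse(rate < ci10k[1L] | rate > ci10k[2L], "outside_10k",
         ifelse(rate < ci100k[1L] | rate > ci100k[2L], "outside_100k", "inside"))
}

#' Estimate empirical Type I error rates for one scenario
#'
#' Runs the full Monte-Carlo pipeline for a single scenario: for each of
#' `nsim` replicates a null dataset is simulated (genotypes independent of
#' phenotypes), the `m` univariate OLS p-values are computed, and the four
#' combination tests (TATES, Simes, Bonferroni minP, effective-number minP)
#' are applied with the scenario's true phenotypic correlation matrix. The
#' empirical Type I error rate per method is the fraction of replicates with
#' combined p-value strictly below `alpha`.
#'
#' Each rate is flagged against the Table-1-style reference confidence
#' intervals at `Nsim = 100,000` and `Nsim = 10,000` (`flags`) and against
#' the interval at the scenario's own `nsim` (`outside_actual`).
#'
#' @param spec A [scenario_spec()].
#' @param keep Number of combined p-values per method to retain in the
#'   result (`0` to discard); retained values feed
#'   [pvalue_distribution()] and rate recomputation at other alpha levels.
#' @param map P-value correlation map used by TATES (see
#'   [pval_correlation_map()]).
#' @param ns_style Correction style for the effective-number minP test
#'   (see [minp_ns()]).
#' @return An object of class `"scenario_summary"` with elements `spec`,
#'   `rates` (named rejection fractions), `counts`, `ci` (at the actual
#'   `nsim`), `flags`, `outside_actual`, and `kept` (a `keep x 4` matrix or
#'   `NULL`).
#' @export
run_scenario <- function(spec, keep = 0, map = "pnorm",
                         ns_style = c("multiplicative", "sidak")) {
  ns_style <- match.arg(ns_style)
  P <- simulate_combined_pvalues(spec, map = map, ns_style = ns_style)
  counts <- colSums(P < spec$alpha)
  rates <- counts / spec$nsim
  ci <- ci95(spec$alpha, spec$nsim)
  structure(
    list(spec = spec,
         rates = rates,
         counts = counts,
         nsim = spec$nsim,
         alpha = spec$alpha,
         ci = ci,
         flags = reference_flag(rates, spec$alpha),
         outside_actual = rates < ci[1L] | rates > ci[2L],
         kept = if (keep > 0) P[seq_len(min(keep, spec$nsim)), , drop = FALSE] else NULL),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  empirical Type I error at alpha = %g (CI %.5f-%.5f):\n",
              x$alpha, x$ci[1L], x$ci[2L]))
  for (mth in names(x$rates)) {
    cat(sprintf("    %-10s %.5f  [%s]\n", mth, x$rates[[mth]], x$flags[[mth]]))
  }
  invisible(x)
}

#' Recompute rejection rates at another significance level
#'
#' Uses the combined p-values retained by [run_scenario()] (`keep > 0`) to
#' recount rejections at a different `alpha` without re-simulating.
#'
#' @param summary A `"scenario_summary"` with a non-`NULL` `kept` matrix.
#' @param alpha Significance level, in `(0, 1)`.
#' @return Named vector of rejection fractions.
#' @export
rates_at_alpha <- function(summary, alpha) {
  stopifnot(inherits(summary, "scenario_summary"))
  if (is.null(summary$kept)) stop("run_scenario() was called with keep = 0", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  colMeans(summary$kept < alpha)
}

#' The 20-scenario compound-symmetry grid
#'
#' Builds the scenario list crossing `m` phenotypes in `{2, 4, 8, 16}` with
#' compound-symmetric correlations `r` in `{0.1, 0.3, 0.5, 0.7, 0.9}`, with
#' `N = 2000` subjects and an unassociated variant at `MAF = 0.5`.
#' Per-scenario seeds are derived deterministically from `seed`.
#'
#' @param nsim Replicates per scenario.
#' @param alpha Nominal significance level.
#' @param n Subjects per replicate.
#' @param maf Minor allele frequency.
#' @param seed Base seed from which the 20 scenario seeds are derived.
#' @param m_values,r_values Grid axes.
#' @return A list of [scenario_spec()] objects (row-major: `m` outer,
#'   `r` inner).
#' @export
table1_scenarios <- function(nsim = 100000, alpha = 0.05, n = 2000, maf = 0.5,
                             seed = 1, m_values = c(2L, 4L, 8L, 16L),
                             r_values = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  specs <- list()
  k <- 0L
  for (m in m_values) {
    for (r in r_values) {
      k <- k + 1L
      specs[[k]] <- scenario_spec(m = m, r = r, n = n, maf = maf, nsim = nsim,
                                  alpha = alpha, seed = derive_seed(seed, 1000 + k))
    }
  }
  specs
}

summarize_grid <- function(rates, alpha) {
  data.frame(
    method = colnames(rates),
    mean = colMeans(rates),
    sd = if (nrow(rates) > 1L) apply(rates, 2L, stats::sd) else rep(0, ncol(rates)),
    largest_overshoot = pmax(0, apply(rates, 2L, max) - alpha),
    largest_undershoot = pmax(0, alpha - apply(rates, 2L, min)),
    sum_abs_dev = colSums(abs(rates - alpha)),
    row.names = NULL)
}

#' Run a grid of Type I error scenarios
#'
#' Runs [run_scenario()] for every scenario in `specs` and aggregates the
#' per-method rejection rates into the summary rows reported for the
#' 20-scenario grid: mean, SD, largest overshoot above `alpha`, largest
#' undershoot below `alpha`, and the sum of absolute deviations from `alpha`
#' across scenarios. All scenarios must share the same `alpha`.
#'
#' @param specs List of [scenario_spec()] objects, e.g. from
#'   [table1_scenarios()].
#' @inheritParams run_scenario
#' @param verbose Print per-scenario progress.
#' @return An object of class `"grid_result"`: `summaries` (list of
#'   `"scenario_summary"`), `rates` (scenarios x methods matrix), `grid`
#'   (per-method summary data frame), and `alpha`.
#' @export
run_grid <- function(specs, keep = 0, map = "pnorm",
                     ns_style = c("multiplicative", "sidak"), verbose = FALSE) {
  ns_style <- match.arg(ns_style)
  stopifnot(length(specs) >= 1L)
  alphas <- vapply(specs, `[[`, numeric(1), "alpha")
  if (length(unique(alphas)) != 1L) stop("all scenarios must share one alpha", call. = FALSE)
  summaries <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    t0 <- proc.time()[["elapsed"]]
    summaries[[i]] <- run_scenario(specs[[i]], keep = keep, map = map,
                                   ns_style = ns_style)
    if (verbose) {
      message(sprintf("scenario %d/%d (m=%d, r=%s, seed=%d): %.1fs",
                      i, length(specs), specs[[i]]$m,
                      format(specs[[i]]$r), specs[[i]]$seed,
                      proc.time()[["elapsed"]] - t0))
    }
  }
  rates <- do.call(rbind, lapply(summaries, `[[`, "rates"))
  structure(
    list(summaries = summaries, rates = rates,
         grid = summarize_grid(rates, alphas[1L]), alpha = alphas[1L]),
    class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("Type I error grid: %d scenarios at alpha = %g\n",
              nrow(x$rates), x$alpha))
  print(x$grid, digits = 4)
  invisible(x)
}

#' Null distribution of combined p-values
#'
#' Bins the combined p-values of each method into equal-width bins on
#' `[0, 1]` and computes the Kolmogorov-Smirnov distance from the
#' Uniform(0,1) distribution, together with the median. Under the null the
#' univariate p-values are uniform, but the weighted-selection combination
#' p-values are not: equal-weight methods (Bonferroni/effective-number minP)
#' show a right-skewed distribution, while Simes/TATES pile mass at the high
#' end because the largest sorted p-value carries weight 1.
#'
#' @param x A [scenario_spec()] (the scenario is simulated) or a
#'   `"scenario_summary"` from [run_scenario()] with retained p-values.
#' @param n_keep Number of p-values per method to analyse (must not exceed
#'   the scenario's `nsim` or the number retained).
#' @param bins Number of equal-width histogram bins.
#' @param ... Passed to [run_scenario()] when `x` is a scenario spec.
#' @return An object of class `"pvalue_dist"`: `counts` (bins x methods),
#'   `ks` (KS distances), `medians`, `breaks`, and `n`.
#' @export
pvalue_distribution <- function(x, n_keep = 10000, bins = 20, ...) {
  if (inherits(x, "scenario_spec")) {
    if (n_keep > x$nsim) stop("n_keep exceeds nsim", call. = FALSE)
    x <- run_scenario(x, keep = n_keep, ...)
  }
  stopifnot(inherits(x, "scenario_summary"))
  if (is.null(x$kept)) stop("no retained p-values; rerun with keep > 0", call. = FALSE)
  if (n_keep > nrow(x$kept)) stop("n_keep exceeds the number of retained p-values", call. = FALSE)
  P <- x$kept[seq_len(n_keep), , drop = FALSE]
  counts <- apply(P, 2L, function(p) {
    tabulate(pmax(1L, ceiling(p * bins)), nbins = bins)
  })
  ks <- apply(P, 2L, function(p) {
    s <- sort(p); i <- seq_along(s)
    max(i / n_keep - s, s - (i - 1) / n_keep)
  })
  structure(
    list(counts = counts, ks = ks, medians = apply(P, 2L, stats::median),
         breaks = seq(0, 1, length.out = bins + 1L), n = n_keep),
    class = "pvalue_dist")
}

#' @export
print.pvalue_dist <- function(x, ...) {
  cat(sprintf("Null combined p-value distributions (%d values, %d bins)\n",
              x$n, nrow(x$counts)))
  for (mth in colnames(x$counts)) {
    cat(sprintf("  %-10s KS distance %.4f, median %.3f\n",
                mth, x$ks[[mth]], x$medians[[mth]]))
  }
  invisible(x)
}
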