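test_that("confidence intervals follow the binomial SE formula", {
  # hand arithmetic: SE = sqrt(0.5*0.5/4) = 0.25
  expect_equal(ci95(0.5, 4), c(lower = 0.01, upper = 0.99))
  ci <- ci95(0.03, 5000)
  expect_equal(unname(mean(ci)), 0.03)  # symmetric about p
  # width scales as 1/sqrt(nsim)
  w1 <- diff(ci95(0.05, 1000)); w2 <- diff(ci95(0.05, 4000))
  expect_equal(unname(w1 / w2), 2)
  expect_error(ci95(0, 100), "strictly between")
  expect_error(ci95(1, 100), "strictly between")
})

test_that("scenario runs are deterministic and batch-extension stable", {
  sp <- scenario_spec(m = 2, r = 0.5, n = 200, maf = 0.5, nsim = 400, seed = 31)
  s1 <- run_scenario(sp, keep = 400)
  s2 <- run_scenario(sp, keep = 400)
  expect_identical(s1$kept, s2$kept)
  expect_identical(s1$rates, s2$rates)

  # extending nsim preserves the earlier replicates (per-batch substreams)
  sp_long <- scenario_spec(m = 2, r = 0.5, n = 200, maf = 0.5, nsim = 800, seed = 31)
  s3 <- run_scenario(sp_long, keep = 800)
  expect_identical(s3$kept[1:400, ], s1$kept)
})

test_that("an m = 1 scenario reduces all four tests to the univariate test", {
  sp <- scenario_spec(m = 1, r = 0, n = 100, maf = 0.5, nsim = 500, seed = 37)
  s <- run_scenario(sp, keep = 500)
  expect_equal(s$kept[, "tates"], s$kept[, "simes"])
  expect_equal(s$kept[, "simes"], s$kept[, "minp_bonf"])
  expect_equal(s$kept[, "minp_bonf"], s$kept[, "minp_ns"])
  expect_true(all(s$rates == s$rates[[1]]))
})

test_that("per-replicate rejection ordering forces rate ordering", {
  sp <- scenario_spec(m = 4, r = 0.7, n = 200, maf = 0.5, nsim = 1000, seed = 41)
  s <- run_scenario(sp, keep = 1000)
  # minP_Bonf >= Simes and >= minP_NS pointwise, so its rate is the smallest
  expect_true(all(s$kept[, "minp_bonf"] >= s$kept[, "simes"] - 1e-12))
  expect_true(all(s$kept[, "minp_bonf"] >= s$kept[, "minp_ns"] - 1e-12))
  expect_lte(s$rates[["minp_bonf"]], s$rates[["simes"]])
  expect_lte(s$rates[["minp_bonf"]], s$rates[["minp_ns"]])
})

test_that("uncorrelated phenotypes give the closed-form calibration rates", {
  sp <- scenario_spec(m = 4, r = 0, n = 200, maf = 0.5, nsim = 4000, seed = 43)
  s <- run_scenario(sp)
  se <- sqrt(0.05 * 0.95 / sp$nsim)
  expect_lt(abs(s$rates[["simes"]] - 0.05), 3 * se)                  # Simes' theorem
  bonf_expected <- 1 - (1 - 0.05 / 4)^4
  expect_lt(abs(s$rates[["minp_bonf"]] - bonf_expected), 3 * se)
})

test_that("grid summaries aggregate rates as mean/sd/overshoot/undershoot", {
  specs <- list(scenario_spec(m = 2, r = 0.3, n = 150, maf = 0.5, nsim = 300, seed = 1),
                scenario_spec(m = 3, r = 0.7, n = 150, maf = 0.5, nsim = 300, seed = 2))
  g <- run_grid(specs)
  expect_equal(dim(g$rates), c(2L, 4L))
  for (k in seq_len(4L)) {
    rts <- g$rates[, k]
    expect_equal(g$grid$mean[k], mean(rts))
    expect_equal(g$grid$sd[k], sd(rts))
    expect_equal(g$grid$largest_overshoot[k], max(0, max(rts) - 0.05))
    expect_equal(g$grid$largest_undershoot[k], max(0, 0.05 - min(rts)))
    expect_equal(g$grid$sum_abs_dev[k], sum(abs(rts - 0.05)))
  }
  # single-scenario grid: sd falls back to 0
  g1 <- run_grid(specs[1])
  expect_equal(g1$grid$sd, rep(0, 4))
  expect_equal(g1$grid$mean, unname(g1$rates[1, ]))
})

test_that("the 20-scenario grid constructor crosses m and r with derived seeds", {
  specs <- table1_scenarios(nsim = 10, seed = 5)
  expect_length(specs, 20L)
  expect_equal(vapply(specs, `[[`, integer(1), "m"),
               rep(c(2L, 4L, 8L, 16L), each = 5L))
  expect_equal(vapply(specs, `[[`, numeric(1), "r"),
               rep(c(0.1, 0.3, 0.5, 0.7, 0.9), 4L))
  seeds <- vapply(specs, `[[`, integer(1), "seed")
  expect_equal(anyDuplicated(seeds), 0L)
  expect_identical(seeds, vapply(table1_scenarios(nsim = 10, seed = 5),
                                 `[[`, integer(1), "seed"))
})

test_that("null p-value distributions separate uniform from selection-skewed", {
  # m = 1: the combined p-value is the univariate p, which is uniform
  sp1 <- scenario_spec(m = 1, r = 0, n = 100, maf = 0.5, nsim = 2000, seed = 47)
  d1 <- pvalue_distribution(sp1, n_keep = 2000)
  expect_lt(d1$ks[["tates"]], 1.358 / sqrt(2000))

  # m > 1: Bonferroni minP is right-skewed (median > 0.5)
  sp4 <- scenario_spec(m = 4, r = 0.5, n = 150, maf = 0.5, nsim = 2000, seed = 53)
  d4 <- pvalue_distribution(sp4, n_keep = 2000)
  expect_gt(d4$medians[["minp_bonf"]], 0.5)
  expect_gt(d4$ks[["minp_bonf"]], 1.358 / sqrt(2000))
  expect_equal(colSums(d4$counts), c(tates = 2000, simes = 2000,
                                     minp_bonf = 2000, minp_ns = 2000))
  expect_error(pvalue_distribution(sp4, n_keep = 5000), "exceeds")
})
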