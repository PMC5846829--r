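test_that("ascending sort is stable and tracks the phenotype permutation", {
  s <- sort_ascending(c(0.04, 0.01, 0.9))
  expect_equal(s$sorted, c(0.01, 0.04, 0.9))
  expect_equal(s$order, c(2L, 1L, 3L))

  tie <- sort_ascending(c(0.05, 0.05))
  expect_equal(tie$sorted, c(0.05, 0.05))
  expect_equal(tie$order, c(1L, 2L))

  expect_equal(sort_ascending(0.7), list(sorted = 0.7, order = 1L))
  expect_error(sort_ascending(numeric(0)), "no p-values")
  expect_error(sort_ascending(c(0.2, NA)), "missing")
  expect_error(sort_ascending(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("Simes and Bonferroni minP match their closed-form definitions", {
  expect_equal(simes_test(c(0.01, 0.04, 0.9))$combined_p, 0.03)
  expect_equal(simes_test(0.5)$combined_p, 0.5)
  expect_equal(simes_test(c(0.05, 0.05))$combined_p, 0.05)

  expect_equal(minp_bonf(c(0.01, 0.04))$combined_p, 0.02)
  expect_equal(minp_bonf(0.5)$combined_p, 0.5)
  expect_equal(minp_bonf(c(0.9, 0.95))$combined_p, 1)
  expect_equal(minp_bonf(c(0.9, 0.95))$selected_rank, 1L)
})

test_that("Nyholt effective number follows the eigenvalue-variance formula", {
  expect_equal(nyholt_meff(diag(4)), 4)
  expect_equal(nyholt_meff(compound_symmetric(2, 1)), 1)
  # 2x2 r=0.5: eigenvalues {1.5, 0.5}, Var = 0.5, Meff = 1 + (1 - 0.5/2)
  expect_equal(nyholt_meff(compound_symmetric(2, 0.5)), 1.75)

  set.seed(41)
  for (m in c(2, 3, 5, 8)) {
    R <- random_corr(m)
    meff <- nyholt_meff(R)
    expect_equal(meff, naive_meff(R), tolerance = 1e-12)
    expect_gte(meff, 1)
    expect_lte(meff, m)
  }
  # Meff decreases with growing compound-symmetric correlation
  ms <- sapply(c(0, 0.3, 0.6, 0.9), function(r) nyholt_meff(compound_symmetric(4, r)))
  expect_true(all(diff(ms) < 0))
  expect_error(nyholt_meff(matrix(c(1, 2, 2, 1), 2)), "correlation matrix")
})

test_that("effective-number minP corrects by Meff and never exceeds Bonferroni", {
  p <- c(0.01, 0.04)
  expect_equal(minp_ns(p, diag(2))$combined_p, minp_bonf(p)$combined_p)
  expect_equal(minp_ns(p, compound_symmetric(2, 1))$combined_p, 0.01)
  expect_equal(minp_ns(c(0.02, 0.5), compound_symmetric(2, 0.5))$combined_p,
               1.75 * 0.02)
  # Sidak style: 1 - (1 - p_min)^Meff
  expect_equal(minp_ns(c(0.02, 0.5), compound_symmetric(2, 0.5),
                       style = "sidak")$combined_p, 1 - 0.98^1.75)
  expect_error(minp_ns(c(0.1, 0.2, 0.3), diag(2)), "dimension mismatch")
})

test_that("TATES effective counts follow the eigenvalue-excess equation", {
  expect_equal(tates_effective_counts(diag(3)), c(1, 2, 3))
  expect_equal(tates_effective_counts(compound_symmetric(2, 1)), c(1, 1))
  # 2x2 r=0.5: eigenvalues {1.5, 0.5}; m_e2 = 2 - 0.5
  expect_equal(tates_effective_counts(compound_symmetric(2, 0.5)), c(1, 1.5))
  expect_error(tates_effective_counts(diag(3), perm = c(1L, 1L, 2L)),
               "permutation")
})

test_that("TATES matches the spec examples under the identity map", {
  expect_equal(tates(c(0.01, 0.04, 0.9), diag(3))$combined_p, 0.03)
  expect_equal(tates(c(0.02, 0.5), compound_symmetric(2, 1), map = "identity")$combined_p,
               0.02)
  expect_equal(tates(c(0.02, 0.5), compound_symmetric(2, 0.5), map = "identity")$combined_p,
               min(1.5 * 0.02, 0.5))
})

test_that("combination tests agree with brute-force oracles on random inputs", {
  set.seed(2024)
  for (rep in 1:40) {
    m <- sample(1:4, 1)
    p <- runif(m)
    R <- if (m == 1) matrix(1) else random_corr(m)
    expect_equal(simes_test(p)$combined_p, naive_simes(p), tolerance = 1e-12)
    expect_equal(tates(p, R, map = "identity")$combined_p,
                 naive_tates(p, R), tolerance = 1e-12)
    expect_equal(minp_ns(p, R)$combined_p,
                 min(1, naive_meff(R) * min(p)), tolerance = 1e-12)
  }
})

test_that("ordering, identity-correlation, and weight invariants hold", {
  set.seed(99)
  for (rep in 1:30) {
    m <- sample(1:6, 1)
    p <- runif(m)
    R <- if (m == 1) matrix(1) else random_corr(m)

    rs <- sapply(list(tates(p, R), simes_test(p), minp_bonf(p), minp_ns(p, R)),
                 `[[`, "combined_p")
    expect_true(all(rs >= 0 & rs <= 1))
    expect_lte(simes_test(p)$combined_p, minp_bonf(p)$combined_p)
    expect_lte(minp_ns(p, R)$combined_p, minp_bonf(p)$combined_p)

    # identity correlation: TATES == Simes exactly, minP_NS == minP_Bonf
    I <- diag(m)
    expect_identical(tates(p, I)$combined_p, simes_test(p)$combined_p)
    expect_identical(minp_ns(p, I)$combined_p, minp_bonf(p)$combined_p)

    # all TATES weights >= 1; largest sorted p-value gets weight exactly 1
    tt <- tates(p, R)
    expect_true(all(tt$weights >= 1 - 1e-12))
    expect_equal(tt$weights[m], 1)

    # weighted p-values >= raw p-values before selection
    ps <- sort(p)
    expect_true(all(pmin(1, tt$weights * ps) >= ps - 1e-15))

    if (m == 1) {
      expect_equal(tt$combined_p, p)
      expect_equal(simes_test(p)$combined_p, p)
      expect_equal(minp_bonf(p)$combined_p, p)
      expect_equal(minp_ns(p, R)$combined_p, p)
    }
  }
})

test_that("decreasing any single p-value never increases a combined p-value", {
  set.seed(7)
  for (rep in 1:25) {
    m <- sample(2:5, 1)
    p <- runif(m)
    R <- random_corr(m)
    k <- sample(m, 1)
    p2 <- p
    p2[k] <- p[k] * runif(1)
    for (f in list(function(q) tates(q, R)$combined_p,
                   function(q) simes_test(q)$combined_p,
                   function(q) minp_bonf(q)$combined_p,
                   function(q) minp_ns(q, R)$combined_p)) {
      expect_lte(f(p2), f(p) + 1e-12)
    }
  }
})

test_that("degenerate p-values of 0 and 1 propagate through weighting", {
  expect_equal(minp_bonf(c(0, 0.5))$combined_p, 0)
  expect_equal(tates(c(0, 1), compound_symmetric(2, 0.5))$combined_p, 0)
  expect_equal(simes_test(c(1, 1, 1))$combined_p, 1)
  expect_equal(tates(c(1, 1), compound_symmetric(2, 0.9))$combined_p, 1)
})
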