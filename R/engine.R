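# Vectorized Monte-Carlo engine: simulates nsim independent null replicates
# of (genotypes, phenotypes), computes the m univariate OLS p-values per
# replicate, and applies the four combination tests.  Replicates are
# processed in batches sized so one batch holds ~4e6 phenotype draws; each
# batch draws its genotype stream and its phenotype stream from separate
# seeds derived from (scenario seed, batch index), and phenotype normals are
# laid out replicate-contiguously, so results are reproducible and extending
# nsim preserves the earlier replicates bit for bit.

METHOD_NAMES <- c("tates", "simes", "minp_bonf", "minp_ns")

derive_seed <- function(seed, k) {
  s <- ((as.double(seed) %% 2147483647) * 48271 + as.double(k) * 104729) %% 2147483647
  as.integer(if (s == 0) 1 else s)
}

batch_size_for <- function(n, m) {
  max(1L, as.integer(floor(4e6 / (as.double(n) * m))))
}

# Row-sort a B x m matrix; returns list(sorted, order) where order[b, j] is
# the original column of the j-th smallest entry in row b (stable in ties).
row_sort <- function(P) {
  B <- nrow(P); m <- ncol(P)
  o <- order(row(P), P)  # stable: ties resolved by column-major position
  list(sorted = matrix(P[o], B, m, byrow = TRUE),
       order = matrix(col(P)[o], B, m, byrow = TRUE))
}

row_min_weighted <- function(PS, w) {
  out <- pmin(1, w[1L] * PS[, 1L])
  for (j in seq_along(w)[-1L]) out <- pmin(out, pmin(1, w[j] * PS[, j]))
  out
}

# Returns an nsim x 4 matrix of combined p-values (tates, simes, minp_bonf,
# minp_ns) for the scenario.
simulate_combined_pvalues <- function(spec, map = "pnorm",
                                      ns_style = "multiplicative") {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$m; n <- spec$n; nsim <- spec$nsim
  R <- spec$corr
  Lf <- corr_factor(R)
  meff <- nyholt_meff(R)
  R_p <- pval_correlation_map(R, map)
  w_simes <- m / seq_len(m)

  # TATES weights: for exchangeable (compound-symmetric) matrices every
  # subset of a given size has the same spectrum, so the weights do not
  # depend on the sort permutation and are computed once.
  cs <- is_compound_symmetric(R_p)
  if (cs) {
    mej_cs <- tates_effective_counts(R_p)
    w_tates <- mej_cs[m] / mej_cs
  } else {
    mej_cache <- new.env(parent = emptyenv())
    mej_subset <- function(idx) {  # idx: sorted original indices, length j
      key <- paste(idx, collapse = ",")
      hit <- mej_cache[[key]]
      if (!is.null(hit)) return(hit)
      j <- length(idx)
      lambda <- corr_eigenvalues(R_p[idx, idx, drop = FALSE])
      v <- j - sum((lambda - 1)[lambda > 1])
      assign(key, v, envir = mej_cache)
      v
    }
  }

  B0 <- batch_size_for(n, m)
  nbatch <- ceiling(nsim / B0)
  out <- matrix(NA_real_, nsim, 4L, dimnames = list(NULL, METHOD_NAMES))
  df <- n - 2L
  done <- 0L
  for (b in seq_len(nbatch)) {
    B <- min(B0, nsim - done)
    set.seed(derive_seed(spec$seed, 2L * b))
    g <- stats::rbinom(n * B, 2L, spec$maf)
    set.seed(derive_seed(spec$seed, 2L * b + 1L))
    Z <- array(stats::rnorm(n * m * B), dim = c(n, m, B))
    Y <- matrix(aperm(Z, c(1L, 3L, 2L)), n * B, m) %*% t(Lf)
    grp <- rep(seq_len(B), each = n)
    sx <- rowsum(g, grp, reorder = FALSE)[, 1L]
    sxx <- rowsum(g * g, grp, reorder = FALSE)[, 1L]
    sy <- rowsum(Y, grp, reorder = FALSE)
    syy <- rowsum(Y * Y, grp, reorder = FALSE)
    sxy <- rowsum(g * Y, grp, reorder = FALSE)
    vgg <- sxx - sx^2 / n
    if (any(vgg <= 0)) stop("monomorphic variant", call. = FALSE)
    r <- (sxy - sx * sy / n) / sqrt(vgg * (syy - sy^2 / n))
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    P <- 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)

    rs <- row_sort(P)
    PS <- rs$sorted
    rows <- done + seq_len(B)
    out[rows, "minp_bonf"] <- pmin(1, m * PS[, 1L])
    out[rows, "minp_ns"] <- if (ns_style == "multiplicative") {
      pmin(1, meff * PS[, 1L])
    } else {
      1 - (1 - PS[, 1L])^meff
    }
    out[rows, "simes"] <- row_min_weighted(PS, w_simes)
    if (cs) {
      out[rows, "tates"] <- row_min_weighted(PS, w_tates)
    } else {
      om <- rs$order
      tv <- numeric(B)
      for (i in seq_len(B)) {
        mej <- vapply(seq_len(m),
                      function(j) mej_subset(sort.int(om[i, seq_len(j)])),
                      numeric(1))
        tv[i] <- min(pmin(1, (mej[m] / mej) * PS[i, ]))
      }
      out[rows, "tates"] <- tv
    }
    done <- done + B
  }
  out
}
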