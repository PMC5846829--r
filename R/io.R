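# Tab-delimited readers/writers.  One dialect throughout: TSV, header row,
# '.' decimal.

#' Read a per-SNP p-value table
#'
#' Reads a TSV with one row per SNP and `m` columns of univariate p-values.
#' If the first column is non-numeric it is taken as the SNP identifier;
#' otherwise identifiers `snp_1, snp_2, ...` are assigned.
#'
#' @param path Path to a TSV file with a header row.
#' @return Numeric matrix of p-values with SNP identifiers as row names.
#' @export
read_pvalue_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (nrow(d) == 0L) stop("empty p-value table", call. = FALSE)
  if (!is.numeric(d[[1L]])) {
    ids <- as.character(d[[1L]])
    d <- d[, -1L, drop = FALSE]
  } else {
    ids <- paste0("snp_", seq_len(nrow(d)))
  }
  M <- as.matrix(d)
  if (!is.numeric(M)) {
    bad <- which(!vapply(d, is.numeric, logical(1)))
    stop(sprintf("malformed number in p-value column '%s'",
                 colnames(d)[bad[1L]]), call. = FALSE)
  }
  rownames(M) <- ids
  for (i in seq_len(nrow(M))) {
    if (anyNA(M[i, ]) || any(M[i, ] < 0 | M[i, ] > 1)) {
      stop(sprintf("invalid p-values in row %d (%s)", i, ids[i]), call. = FALSE)
    }
  }
  M
}

#' Read a correlation matrix from TSV
#'
#' Reads a square TSV with a header row and a leading column of phenotype
#' names, validates symmetry, unit diagonal, and positive
#' semi-definiteness, and returns the matrix.
#'
#' @param path Path to the TSV file.
#' @return A valid correlation matrix with dimnames.
#' @export
read_correlation_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE)
  M <- as.matrix(d)
  if (!is.numeric(M)) stop("malformed number in correlation matrix", call. = FALSE)
  check_corr(M)
}

#' Write a correlation matrix to TSV
#'
#' Full-precision writer; [read_correlation_matrix()] round-trips it
#' exactly.
#'
#' @param R Correlation matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_correlation_matrix <- function(R, path) {
  R <- check_corr(R)
  nm <- colnames(R)
  if (is.null(nm)) nm <- paste0("pheno_", seq_len(ncol(R)))
  d <- data.frame(phenotype = nm,
                  matrix(sprintf("%.17g", R), nrow(R), ncol(R)),
                  check.names = FALSE)
  colnames(d) <- c("phenotype", nm)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply combination tests to a table of per-SNP p-values
#'
#' Runs the selected combination tests on each row of a p-value matrix and
#' returns one long row per SNP per method.
#'
#' @param pmat Numeric matrix (SNPs x phenotypes) of univariate p-values,
#'   SNP identifiers as row names (see [read_pvalue_table()]).
#' @param R Phenotypic correlation matrix; required for `tates` and
#'   `minp_ns`.
#' @param methods Character subset of
#'   `c("tates", "simes", "minp_bonf", "minp_ns")`, or `"all"`.
#' @param map,ns_style Passed to [tates()] and [minp_ns()].
#' @return Data frame with columns `snp_id`, `method`, `combined_p`,
#'   `selected_rank`.
#' @export
combine_tests <- function(pmat, R = NULL,
                          methods = "all", map = "pnorm",
                          ns_style = c("multiplicative", "sidak")) {
  ns_style <- match.arg(ns_style)
  pmat <- as.matrix(pmat)
  if (identical(methods, "all")) methods <- METHOD_NAMES
  methods <- match.arg(methods, METHOD_NAMES, several.ok = TRUE)
  needs_R <- any(methods %in% c("tates", "minp_ns"))
  if (needs_R) {
    if (is.null(R)) stop("a correlation matrix is required for tates/minp_ns",
                         call. = FALSE)
    R <- check_corr(R)
    if (nrow(R) != ncol(pmat)) {
      stop("correlation matrix dimension does not match the number of p-value columns",
           call. = FALSE)
    }
  }
  ids <- rownames(pmat)
  if (is.null(ids)) ids <- paste0("snp_", seq_len(nrow(pmat)))
  rows <- vector("list", nrow(pmat) * length(methods))
  k <- 0L
  for (i in seq_len(nrow(pmat))) {
    p <- pmat[i, ]
    for (mth in methods) {
      res <- switch(mth,
                    tates = tates(p, R, map = map),
                    simes = simes_test(p),
                    minp_bonf = minp_bonf(p),
                    minp_ns = minp_ns(p, R, style = ns_style))
      k <- k + 1L
      rows[[k]] <- data.frame(snp_id = ids[i], method = mth,
                              combined_p = res$combined_p,
                              selected_rank = res$selected_rank)
    }
  }
  do.call(rbind, rows)
}

#' Export a simulated dataset to TSV
#'
#' Writes a null dataset as columns `genotype, pheno_1, ..., pheno_m`.
#'
#' @param data A `"null_dataset"` from [simulate_null_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dataset_tsv <- function(data, path) {
  d <- data.frame(genotype = data$genotypes, data$phenotypes,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export grid results as a Type-I-error table
#'
#' Formats a [run_grid()] result as the grid table: one row per scenario
#' (columns `m`, `r`, the four per-method rates and their reference CI
#' flags) followed by the per-method summary rows (mean, SD, largest
#' overshoot, largest undershoot, sum of absolute deviations).
#'
#' @param grid A `"grid_result"`.
#' @return Data frame; write with [write_grid_tsv()].
#' @export
as_grid_table <- function(grid) {
  stopifnot(inherits(grid, "grid_result"))
  meths <- colnames(grid$rates)
  rows <- lapply(grid$summaries, function(s) {
    cells <- as.list(c(s$rates, stats::setNames(s$flags, paste0(meths, "_flag"))))
    data.frame(m = s$spec$m,
               r = if (is.na(s$spec$r)) NA_real_ else s$spec$r,
               cells, check.names = FALSE)
  })
  body <- do.call(rbind, rows)
  g <- grid$grid
  summary_rows <- data.frame(
    m = NA_integer_, r = NA_real_,
    stat = c("mean", "sd", "largest_overshoot", "largest_undershoot", "sum_abs_dev"),
    t(cbind(g$mean, g$sd, g$largest_overshoot, g$largest_undershoot, g$sum_abs_dev)),
    check.names = FALSE)
  colnames(summary_rows) <- c("m", "r", "stat", g$method)
  body$stat <- "rate"
  body <- body[, c("m", "r", "stat", meths, paste0(meths, "_flag"))]
  for (fc in paste0(meths, "_flag")) summary_rows[[fc]] <- NA_character_
  rbind(body, summary_rows[, colnames(body)])
}

#' @rdname as_grid_table
#' @param path Output path for the TSV.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(as_grid_table(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
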