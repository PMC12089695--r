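#' Low-expression prefiltering (published default rule)
#'
#' Keeps genes that are expressed at a worthwhile level in enough samples,
#' following the published default counts-per-million rule: with `n` the
#' smallest group size (damped above `large_n` to `large_n + (n - large_n) *
#' min_prop`), a gene is kept iff its CPM is at least `min_count / median
#' library size * 1e6` in at least `n` samples, and its total count across all
#' samples is at least `min_total_count`. Deterministic and invariant to
#' sample and gene order; filtering twice equals filtering once.
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample metadata (used for the group sizes); alternatively
#'   pass `group` directly.
#' @param factor Name of the grouping column in `samples`.
#' @param group Optional grouping vector aligned to the counts columns
#'   (overrides `samples`/`factor`).
#' @param min_count Minimum count in the CPM cutoff (default 10).
#' @param min_total_count Minimum total count across samples (default 15).
#' @param large_n,min_prop Damping of the required sample number for large
#'   groups (defaults 10 and 0.7).
#' @return List with `counts` (the filtered matrix), `keep` (named logical
#'   over input genes), `kept_genes` (character).
#' @export
prefilter <- function(counts, samples = NULL, factor = NULL, group = NULL,
                      min_count = 10, min_total_count = 15,
                      large_n = 10, min_prop = 0.7) {
  counts <- assert_count_matrix(counts)
  if (is.null(group)) {
    if (is.null(samples) || is.null(factor)) {
      abort("Supply either `group`, or `samples` + `factor`.")
    }
    samples <- align_samples(counts, samples)
    group <- samples[[factor]]
  }
  stopifnot(length(group) == ncol(counts),
            min_count >= 0, min_total_count >= 0, large_n >= 0,
            min_prop >= 0, min_prop <= 1)
  lib_size <- colSums(counts)
  n <- min(table(as.character(group)))
  if (n > large_n) n <- large_n + (n - large_n) * min_prop
  cpm_cutoff <- min_count / median(lib_size) * 1e6
  cpm <- sweep(counts, 2, lib_size, "/") * 1e6
  tol <- 1e-14
  keep <- rowSums(cpm >= cpm_cutoff) >= (n - tol) &
    rowSums(counts) >= (min_total_count - tol)
  names(keep) <- rownames(counts)
  if (!any(keep)) {
    warn("Prefiltering removed every gene.")
  }
  list(counts = counts[keep, , drop = FALSE], keep = keep,
       kept_genes = rownames(counts)[keep])
}

#' Simplified surrogate-variable estimation
#'
#' Estimates hidden structure (batch effects and other unwanted variation)
#' from expression residuals by a simplified two-step procedure: (1) regress
#' log2(normalized count + 1) on the known design; (2) take principal
#' components of the residual matrix as candidate surrogate variables. When
#' `n_sv = "auto"`, the number of surrogate variables is chosen by a
#' permutation (parallel-analysis) test: each gene's residuals are permuted
#' independently across samples `B` times, and the leading eigenvalues kept
#' are those exceeding the 95th percentile of their permuted counterparts
#' (stopping at the first non-significant one). This is an approximation of
#' full iteratively-reweighted surrogate-variable analysis, not a
#' re-implementation of it; a full implementation can be substituted upstream
#' by merging its surrogate variables into the sample table.
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample metadata.
#' @param factor Design factor column name.
#' @param n_sv `"auto"` or a fixed integer >= 0.
#' @param B Number of permutations for the auto rule (default 100).
#' @param seed Seed for the permutation test (default 1).
#' @param alpha Significance level for the eigenvalue test (default 0.05 =
#'   the 95th percentile rule).
#' @return List with `n_sv`, `sv` (sample x n_sv matrix, orthonormal,
#'   zero-mean columns, rownames = sample IDs), and `samples` (the metadata
#'   with `SV1..SVn` columns appended, ready to use as covariates).
#' @export
estimate_surrogate_variables <- function(counts, samples, factor,
                                         n_sv = "auto", B = 100, seed = 1,
                                         alpha = 0.05) {
  counts <- assert_count_matrix(counts)
  samples <- align_samples(counts, samples)
  fac <- base::factor(as.character(samples[[factor]]))
  X <- model.matrix(~fac)
  n <- ncol(counts)
  if (n <= ncol(X)) abort("Need more samples than model coefficients.")
  sf <- estimate_size_factors(counts)
  expr <- log2(sweep(counts, 2, sf, "/") + 1)     # genes x samples
  # residuals of each gene on the known design
  H <- X %*% solve(crossprod(X), t(X))            # hat matrix, n x n
  R <- expr - expr %*% t(H)                       # residuals, genes x samples
  Rt <- t(R)                                      # samples x genes
  pc <- prcomp(Rt, center = TRUE, scale. = FALSE)
  max_rank <- n - ncol(X)
  ev <- pc$sdev^2
  if (identical(n_sv, "auto")) {
    # permutation test on eigenvalue *proportions* (scale-free): permute each
    # gene's residuals, re-residualize on the design so ranks match, and keep
    # the leading components whose observed variance share beats the permuted
    # share at level `alpha`, with the p-values monotonized down the scree
    m <- min(max_rank, length(ev))
    dstat <- ev[seq_len(m)] / sum(ev[seq_len(m)])
    perm_prop <- matrix(NA_real_, B, m)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    for (b in seq_len(B)) {
      Rp <- apply(Rt, 2, sample)
      Rp <- Rp - H %*% Rp
      d2 <- svd(scale(Rp, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d[seq_len(m)]^2
      perm_prop[b, ] <- d2 / sum(d2)
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    psv <- vapply(seq_len(m), function(i) mean(perm_prop[, i] >= dstat[i]),
                  numeric(1))
    psv <- cummax(psv)
    k <- sum(psv <= alpha)
  } else {
    k <- as.integer(n_sv)
    if (k < 0) abort("`n_sv` must be >= 0 or 'auto'.")
    if (k > 0 && k >= max_rank) {
      abort(paste0("Requested n_sv = ", k, " >= residual rank (", max_rank, ")."))
    }
  }
  if (k > 0) {
    sv <- pc$x[, seq_len(k), drop = FALSE]
    sv <- sweep(sv, 2, sqrt(colSums(sv^2)), "/")  # unit-norm, already orthogonal
    colnames(sv) <- paste0("SV", seq_len(k))
    rownames(sv) <- colnames(counts)
  } else {
    sv <- matrix(numeric(0), nrow = n, ncol = 0,
                 dimnames = list(colnames(counts), NULL))
  }
  out_samples <- samples
  for (j in seq_len(k)) out_samples[[paste0("SV", j)]] <- sv[, j]
  list(n_sv = k, sv = sv, samples = out_samples)
}

#' Write surrogate variables as a CSV mergeable into the metadata
#'
#' @param svres Result of [estimate_surrogate_variables()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sv_csv <- function(svres, path) {
  df <- data.frame(sample_id = rownames(svres$sv), svres$sv,
                   check.names = FALSE)
  write_table_csv(df, path)
}
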