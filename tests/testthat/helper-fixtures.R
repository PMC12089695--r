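# small in-code fixtures shared across tests

# tiny deterministic counts matrix
tiny_counts <- function() {
  matrix(c(10, 20, 30, 40,
           5, 0, 15, 25,
           100, 120, 90, 110),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("geneA", "geneB", "geneC"),
                         c("s1", "s2", "s3", "s4")))
}

tiny_samples <- function() {
  tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                 group = factor(c("A", "A", "B", "B")))
}

# small simulated dataset for engine-level tests
quick_sim <- function(seed = 101, n_genes = 200,
                      group_sizes = c(A = 5, B = 5, C = 5), ...) {
  simulate_dataset(sim_config(n_genes = n_genes, group_sizes = group_sizes,
                              sparse_fraction = 0, seed = seed, ...))
}

# a sparse/high-dispersion dataset where ridge shrinkage is reference-dependent
sparse_sim <- function(seed = 202, n_genes = 400) {
  simulate_dataset(sim_config(
    n_genes = n_genes, group_sizes = c(A = 5, B = 5, C = 5),
    sparse_fraction = 0.3, sparse_disp_multiplier = 8, seed = seed))
}

# brute-force exclusive intersections: loop over all 2^k - 1 membership
# patterns, computing each by raw intersect/setdiff set algebra
brute_force_intersections <- function(sets) {
  k <- length(sets)
  nm <- names(sets)
  out <- list()
  for (code in 1:(2^k - 1)) {
    inset <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))
    genes <- Reduce(intersect, sets[inset])
    for (s in sets[!inset]) genes <- setdiff(genes, s)
    if (length(genes) > 0) {
      out[[paste(nm[inset], collapse = "&")]] <- sort(genes)
    }
  }
  out
}

# direct transcription of the published default low-count filter rule,
# written independently of the package's prefilter()
reference_filter_rule <- function(counts, group, min_count = 10,
                                  min_total_count = 15, large_n = 10,
                                  min_prop = 0.7) {
  lib <- colSums(counts)
  n_min <- min(table(group))
  if (n_min > large_n) n_min <- large_n + (n_min - large_n) * min_prop
  cutoff <- min_count / stats::median(lib) * 1e6
  cpm <- t(t(counts) / lib) * 1e6
  keep1 <- rowSums(cpm >= cutoff) >= n_min - 1e-14
  keep2 <- rowSums(counts) >= min_total_count - 1e-14
  keep1 & keep2
}

# build a deg_set tibble directly (for set-algebra tests)
make_degset <- function(genes, contrast, directions = NULL,
                        alpha = 0.01, lfc_min = 2) {
  directions <- directions %||% rep(1L, length(genes))
  d <- tibble::tibble(gene = genes, direction = directions,
                      log2FoldChange = 3 * directions,
                      padj = rep(1e-4, length(genes)),
                      contrast = contrast, alpha = alpha, lfc_min = lfc_min)
  class(d) <- c("deg_set", class(d))
  d
}

`%||%` <- function(x, y) if (is.null(x)) y else x
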