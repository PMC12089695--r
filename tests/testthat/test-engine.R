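test_that("size factors: symmetry, median-of-ratios closed form, scaling invariance", {
  m <- matrix(c(10, 10, 50, 50, 200, 200), 3, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- m; m2[, 2] <- 2 * m[, 1]
  expect_equal(unname(estimate_size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # the median-of-ratios formula is invariant under a global rescaling
  expect_equal(estimate_size_factors(m2 * 10), estimate_size_factors(m2),
               tolerance = 1e-12)
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  set.seed(5)
  m <- matrix(rnbinom(600, mu = 100, size = 5), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("size factor degenerate inputs", {
  m0 <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(estimate_size_factors(m0), "zero")
  # no all-positive gene: falls back with a warning
  m1 <- matrix(c(5, 0, 0, 7), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(sf <- estimate_size_factors(m1), "positive")
  expect_true(all(sf > 0))
})

test_that("BH adjustment: hand-checked step-up, NA passthrough, validation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(c(NA_real_, NA_real_)), c(NA_real_, NA_real_))
  # missing entries do not count toward m
  expect_equal(bh_adjust(c(0.01, NA, 0.02, 0.03)),
               c(0.03, NA, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("unshrunk mirror identity: LFCs negate, p-values match, baseMean invariant", {
  sim <- quick_sim(seed = 11, n_genes = 150)
  run <- suppressMessages(run_all_contrasts(sim$counts, sim$samples, "group"))
  pairs <- reciprocal_pairs(run)
  for (i in seq_len(nrow(pairs))) {
    f <- run$tables[[pairs$forward[i]]]
    r <- run$tables[[pairs$reverse[i]]]
    ok <- !is.na(f$pvalue) & !is.na(r$pvalue)
    expect_gt(mean(ok), 0.95)
    expect_lt(max(abs(f$log2FoldChange + r$log2FoldChange)[ok]), 1e-6)
    expect_equal(f$pvalue[ok], r$pvalue[ok], tolerance = 1e-6)
    expect_identical(f$baseMean, r$baseMean)
  }
  # baseMean is identical across every contrast of the dataset
  bm <- sapply(run$tables, function(t) t$baseMean)
  expect_true(all(abs(bm - bm[, 1]) < 1e-12))
})

test_that("padj is monotone nondecreasing in p over the tested set", {
  sim <- quick_sim(seed = 12, n_genes = 150)
  tab <- fit_and_test(sim$counts, sim$samples, "group", "A")[["B-A"]]
  ok <- !is.na(tab$pvalue)
  o <- order(tab$pvalue[ok])
  expect_true(all(diff(tab$padj[ok][o]) >= -1e-12))
  expect_true(all(tab$padj[ok] >= tab$pvalue[ok] - 1e-12))
})

test_that("null genes estimate LFC near 0 and a 4-fold gene near 2", {
  # two groups with identical, large, near-replicate counts: LFC within
  # +/-0.05 of 0 for >= 95% of genes
  sim <- simulate_dataset(sim_config(
    n_genes = 300, group_sizes = c(A = 20, B = 20),
    baseline_meanlog = log(1000), baseline_sdlog = 0.1,
    disp_asymptote = 0.001, disp_lowcount = 0, disp_sdlog = 0,
    de_fraction = 0, sparse_fraction = 0, libsize_sdlog = 0, seed = 33))
  tab <- fit_and_test(sim$counts, sim$samples, "group", "A")[["B-A"]]
  expect_gt(mean(abs(tab$log2FoldChange) < 0.05, na.rm = TRUE), 0.95)

  # normalized group means 100 vs 400, low dispersion: LFC within +/-0.3 of 2
  # (stable background genes pin the size factors near 1)
  set.seed(34)
  m <- rbind(gene1 = c(rnbinom(10, mu = 100, size = 100),
                       rnbinom(10, mu = 400, size = 100)),
             matrix(rnbinom(40 * 20, mu = 300, size = 100), 40, 20,
                    dimnames = list(sprintf("bg%02d", 1:40), NULL)))
  colnames(m) <- paste0("s", 1:20)
  meta <- tibble::tibble(sample_id = colnames(m),
                         group = factor(rep(c("A", "B"), each = 10)))
  tab2 <- fit_and_test(m, meta, "group", "A")[["B-A"]]
  expect_lt(abs(tab2$log2FoldChange[tab2$gene == "gene1"] - 2), 0.3)
})

test_that("engine contract errors", {
  sim <- quick_sim(seed = 13, n_genes = 20)
  expect_error(fit_dge(sim$counts, sim$samples, "group", "Z"), "not a level")
  # collinear covariate
  smp <- sim$samples
  smp$dup <- as.integer(smp$group == "B")
  smp$dup2 <- smp$dup
  expect_error(
    fit_dge(sim$counts, smp, "group", "A", covariates = c("dup", "dup2")),
    "rank-deficient")
  # a level with one sample fails at fit time
  smp2 <- sim$samples[-(1:4), ]
  cts2 <- sim$counts[, smp2$sample_id]
  expect_error(fit_dge(cts2, smp2, "group", "A"), ">= 2 samples")
})

test_that("ridge shrinkage: flat-prior limit and weak shrinkage toward zero (k=2)", {
  sim <- quick_sim(seed = 14, n_genes = 120, group_sizes = c(A = 5, B = 5))
  fit <- suppressMessages(fit_dge(sim$counts, sim$samples, "group", "A"))
  none <- contrast_results(fit, "B", mode = "none")
  flat <- shrink_lfc(none, fit, engine_config(mode = "ridge", prior_sd = 1e6))
  ok <- !is.na(none$pvalue)
  expect_lt(max(abs(flat$log2FoldChange - none$log2FoldChange)[ok]), 1e-4)

  ridge <- shrink_lfc(none, fit, engine_config(mode = "ridge", prior_sd = 0.5))
  expect_true(all((abs(ridge$log2FoldChange) <=
                     abs(none$log2FoldChange) + 1e-8)[ok]))
  expect_identical(ridge$pvalue, none$pvalue)
  expect_identical(ridge$padj, none$padj)
})

test_that("ridge shrinkage is symmetric for k=2 but reference-dependent for k=3", {
  sim <- sparse_sim(seed = 21, n_genes = 300)
  cfg <- engine_config(mode = "ridge", prior_sd = 0.5)

  # k=2 restriction: single coefficient, exact antisymmetry
  sel <- sim$samples$group %in% c("A", "B")
  smp <- sim$samples[sel, ]; smp$group <- droplevels(smp$group)
  r2 <- suppressMessages(run_all_contrasts(sim$counts[, smp$sample_id], smp,
                                           "group", config = cfg))
  s2 <- r2$tables[["B-A"]]$log2FoldChange + r2$tables[["A-B"]]$log2FoldChange
  ok2 <- !is.na(r2$tables[["B-A"]]$pvalue)
  expect_lt(max(abs(s2[ok2])), 1e-6)

  # k=3: at least one sparse high-dispersion gene fails to mirror
  r3 <- suppressMessages(run_all_contrasts(sim$counts, sim$samples, "group",
                                           config = cfg))
  s3 <- r3$tables[["B-A"]]$log2FoldChange + r3$tables[["A-B"]]$log2FoldChange
  sparse <- sim$truth$sparse
  expect_gt(max(abs(s3[sparse]), na.rm = TRUE), 0.1)
})

test_that("backend registry validates and dispatches", {
  expect_error(shrink_lfc(tibble::tibble(contrast = "B-A"),
                          structure(list(reference = "A"), class = "dge_fit"),
                          engine_config(mode = "backend:nope")),
               "No shrinkage backend")
  register_shrinkage_backend("passthrough",
    function(counts, samples, factor, reference, mode) {
      list(`B-A` = tibble::tibble(gene = rownames(counts), baseMean = 1,
                                  log2FoldChange = 0, lfcSE = 1,
                                  pvalue = 1, padj = 1))
    })
  expect_true("passthrough" %in% list_shrinkage_backends())
  sim <- quick_sim(seed = 15, n_genes = 10, group_sizes = c(A = 3, B = 3))
  fit <- suppressMessages(fit_dge(sim$counts, sim$samples, "group", "A"))
  tab <- contrast_results(fit, "B")
  out <- shrink_lfc(tab, fit, engine_config(mode = "backend:passthrough"))
  expect_identical(nrow(out), nrow(sim$counts))
})

test_that("unshrunk LFC agrees with an independent NB-GLM fit on a tiny fixture", {
  # independent oracle: MASS::glm.nb-free check via edgeR's exact NB machinery
  # is not aligned with a Wald LFC, so use a saturated two-group closed form:
  # with equal size factors and a common dispersion, the MLE of the group
  # log-ratio is log2(mean(B)/mean(A))
  set.seed(77)
  m <- matrix(rnbinom(8 * 40, mu = 500, size = 50), 40, 8,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:8)))
  meta <- tibble::tibble(sample_id = colnames(m),
                         group = factor(rep(c("A", "B"), each = 4)))
  fit <- suppressMessages(fit_dge(m, meta, "group", "A"))
  tab <- contrast_results(fit, "B")
  sf <- estimate_size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  closed <- log2(rowMeans(norm[, 5:8]) / rowMeans(norm[, 1:4]))
  # the NB Wald MLE in a saturated one-factor design equals the ratio of
  # normalized group means only exactly at dispersion 0; at small dispersion
  # they agree closely
  expect_equal(unname(tab$log2FoldChange), unname(closed), tolerance = 0.05)
})
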