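#' Simulation configuration
#'
#' Parameters for the seeded negative-binomial count simulator. Counts are
#' drawn independently as NB with mean
#' `L_j * B(g, j) * q_g * 2^effect(g, group(j))` and per-gene dispersion
#' `alpha_g` (variance `mu + alpha * mu^2`): `q_g` is the log-normal baseline
#' mean, `L_j` a log-normal library-size factor, `B` an optional hidden-batch
#' multiplier, and effects are log2-additive so truth is recoverable on the
#' engine's own scale.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector: samples per group level (k >= 2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline mean for non-sparse genes.
#' @param disp_asymptote,disp_lowcount,disp_sdlog Per-gene NB dispersion is
#'   drawn around the canonical decreasing mean-dispersion trend
#'   `a0 + a1 / mean` (`a0 = disp_asymptote`, `a1 = disp_lowcount`) with
#'   multiplicative log-normal noise of sd `disp_sdlog`, so low-count genes
#'   are intrinsically noisier, as in real RNA-seq.
#' @param de_fraction Fraction of genes carrying true group effects.
#' @param effect_prob For a DE gene, probability each non-baseline group gets
#'   a nonzero effect (so contrasts between non-baseline groups are also DE).
#' @param effect_meanlog,effect_sdlog Log-normal parameters of the absolute
#'   log2 effect magnitude; sign is random.
#' @param sparse_fraction Fraction of genes forced to a sparse baseline.
#' @param sparse_mean_cap Upper bound of the sparse genes' baseline mean
#'   (default 5; sparse baselines are uniform on (0.2, cap)).
#' @param sparse_disp_multiplier Multiplier on sparse genes' dispersion
#'   (default 1; clinical-like scenarios use larger values).
#' @param batch `NULL`, or a list
#'   `list(n_batches = 2, frac_genes, sdlog2, group_props = NULL)`: a hidden
#'   batch multiplying the mean of affected genes (fraction `frac_genes`) by
#'   `2^N(0, sdlog2)` per gene in the non-reference batch. With
#'   `group_props = NULL` the batch is assigned in balance within each group
#'   (orthogonal to the design); a numeric vector of per-group batch-1
#'   proportions (recycled over groups) instead creates partial
#'   group-batch confounding, the regime where hidden structure produces
#'   spurious effects that only covariate adjustment can remove.
#' @param libsize_sdlog Log-normal sd of the library-size factors.
#' @param seed Mandatory integer seed; all randomness flows from it through
#'   fixed offsets for the gene-level, sample-level and count-noise stages,
#'   so partial re-simulation is stable.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = c(A = 5, B = 5, C = 5),
                       baseline_meanlog = log(200), baseline_sdlog = 1.2,
                       disp_asymptote = 0.05, disp_lowcount = 1,
                       disp_sdlog = 0.4,
                       de_fraction = 0.3, effect_prob = 0.7,
                       effect_meanlog = log(3), effect_sdlog = 0.5,
                       sparse_fraction = 0.1, sparse_mean_cap = 5,
                       sparse_disp_multiplier = 1,
                       batch = NULL, libsize_sdlog = 0.15, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  stopifnot(n_genes >= 1, length(group_sizes) >= 2, all(group_sizes >= 1),
            de_fraction >= 0, de_fraction <= 1,
            sparse_fraction >= 0, sparse_fraction <= 1,
            effect_prob >= 0, effect_prob <= 1,
            sparse_mean_cap > 0.2, sparse_disp_multiplier > 0)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  }
  if (!is.null(batch)) {
    batch <- modifyList(list(n_batches = 2, frac_genes = 0.3, sdlog2 = 1,
                             group_props = NULL), batch)
  }
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 disp_asymptote = disp_asymptote,
                 disp_lowcount = disp_lowcount, disp_sdlog = disp_sdlog,
                 de_fraction = de_fraction, effect_prob = effect_prob,
                 effect_meanlog = effect_meanlog, effect_sdlog = effect_sdlog,
                 sparse_fraction = sparse_fraction,
                 sparse_mean_cap = sparse_mean_cap,
                 sparse_disp_multiplier = sparse_disp_multiplier,
                 batch = batch, libsize_sdlog = libsize_sdlog,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Scenario presets emulating three data archetypes
#'
#' * `cellline` — tight in-vitro replicates: six groups of 3, very low
#'   dispersion (around 0.01), few sparse genes. Expected to pass the mirror
#'   check essentially everywhere without cleaning.
#' * `clinical` — variable patient cohorts: four unequal groups, high and
#'   heterogeneous dispersion (upper tail around 2), 30% sparse low-count
#'   genes with extra dispersion — the regime where shrinkage
#'   reference-dependence shows up.
#' * `batch` — the clinical scenario plus a strong hidden 2-level batch
#'   multiplying 30% of genes (typical fold around 2.8), partially confounded
#'   with the groups (batch-1 share falling from 0.8 to 0.2 across severity),
#'   emulating cohorts collected over time; the regime where hidden structure
#'   produces spurious effects and surrogate-variable adjustment (not
#'   prefiltering) is the appropriate cleaning step.
#'
#' @param name One of `"cellline"`, `"clinical"`, `"batch"`.
#' @param seed Seed forwarded to [sim_config()].
#' @param n_genes Number of genes (default 2000).
#' @return A `sim_config`.
#' @export
scenario_preset <- function(name, seed, n_genes = 2000) {
  presets <- c("cellline", "clinical", "batch")
  if (!name %in% presets) {
    abort(paste0("Unknown preset '", name, "'. Available: ",
                 paste(presets, collapse = ", "), "."))
  }
  switch(name,
    cellline = sim_config(
      n_genes = n_genes,
      group_sizes = c(CLAT0 = 3, CLAT1 = 3, CLAT2 = 3,
                      CLBT0 = 3, CLBT1 = 3, CLBT2 = 3),
      baseline_meanlog = log(250), baseline_sdlog = 1.2,
      disp_asymptote = 0.01, disp_lowcount = 0.3, disp_sdlog = 0.3,
      de_fraction = 0.3, sparse_fraction = 0.05, sparse_disp_multiplier = 1,
      seed = seed),
    clinical = sim_config(
      n_genes = n_genes,
      group_sizes = c(Ctrl = 6, Mild = 8, Mod = 7, Severe = 5),
      baseline_meanlog = log(200), baseline_sdlog = 1.2,
      disp_asymptote = 0.2, disp_lowcount = 3, disp_sdlog = 0.5,
      de_fraction = 0.3, sparse_fraction = 0.3, sparse_disp_multiplier = 2,
      seed = seed),
    batch = sim_config(
      n_genes = n_genes,
      group_sizes = c(Ctrl = 6, Mild = 8, Mod = 7, Severe = 5),
      baseline_meanlog = log(200), baseline_sdlog = 1.2,
      disp_asymptote = 0.2, disp_lowcount = 3, disp_sdlog = 0.5,
      de_fraction = 0.3, sparse_fraction = 0.3, sparse_disp_multiplier = 2,
      batch = list(n_batches = 2, frac_genes = 0.3, sdlog2 = 1.5,
                   group_props = c(0.8, 0.65, 0.35, 0.2)),
      seed = seed))
}

#' Simulate a multi-group NB count dataset with ground truth
#'
#' @param config A [sim_config()] (or [scenario_preset()]).
#' @return A `sim_dataset` list: `counts` (gene x sample integer matrix),
#'   `samples` (tibble with `sample_id`, `group`, and `batch` when simulated),
#'   `truth` (list: `effects` gene x group log2 matrix, `dispersion`,
#'   `baseline_mean`, `sparse` flags, `lib_factors`, `batch_multiplier_log2`,
#'   `batch` assignment), and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  G <- cf$n_genes
  groups <- names(cf$group_sizes)
  k <- length(groups)
  n <- sum(cf$group_sizes)
  gene_ids <- sprintf("gene%04d", seq_len(G))
  group_of <- rep(groups, cf$group_sizes)
  sample_ids <- paste0(group_of, "_", unlist(lapply(cf$group_sizes, seq_len)))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  # stream 1: gene-level parameters
  set.seed(cf$seed)
  n_sparse <- round(cf$sparse_fraction * G)
  sparse <- rep(FALSE, G)
  if (n_sparse > 0) sparse[sample.int(G, n_sparse)] <- TRUE
  baseline <- rlnorm(G, cf$baseline_meanlog, cf$baseline_sdlog)
  baseline[sparse] <- runif(n_sparse, 0.2, cf$sparse_mean_cap)
  dispersion <- (cf$disp_asymptote + cf$disp_lowcount / baseline) *
    rlnorm(G, 0, cf$disp_sdlog)
  dispersion[sparse] <- dispersion[sparse] * cf$sparse_disp_multiplier
  is_de <- runif(G) < cf$de_fraction
  effects <- matrix(0, G, k, dimnames = list(gene_ids, groups))
  for (j in seq_len(k)[-1]) {
    hit <- is_de & (runif(G) < cf$effect_prob)
    mag <- rlnorm(G, cf$effect_meanlog, cf$effect_sdlog)
    sgn <- sign(runif(G) - 0.5)
    effects[hit, j] <- (mag * sgn)[hit]
  }
  batch_mult_log2 <- rep(0, G)
  if (!is.null(cf$batch)) {
    affected <- runif(G) < cf$batch$frac_genes
    batch_mult_log2[affected] <- rnorm(sum(affected), 0, cf$batch$sdlog2)
  }

  # stream 2: sample-level parameters
  set.seed(cf$seed + 1L)
  lib_factors <- rlnorm(n, 0, cf$libsize_sdlog)
  batch_of <- rep(1L, n)
  if (!is.null(cf$batch)) {
    if (is.null(cf$batch$group_props)) {
      # balanced assignment within each group: batch orthogonal to the design
      for (g in groups) {
        idx <- which(group_of == g)
        batch_of[idx] <- rep(seq_len(cf$batch$n_batches), length.out = length(idx))
      }
    } else {
      props <- rep(cf$batch$group_props, length.out = k)
      for (gi in seq_len(k)) {
        idx <- which(group_of == groups[gi])
        n1 <- min(max(round(props[gi] * length(idx)), 1L), length(idx) - 1L)
        batch_of[idx] <- c(rep(1L, n1), rep(2L, length(idx) - n1))
      }
    }
  }

  # stream 3: count noise
  set.seed(cf$seed + 2L)
  mu <- matrix(0, G, n)
  for (j in seq_len(n)) {
    eff <- effects[, match(group_of[j], groups)]
    bmul <- if (batch_of[j] > 1L) 2^batch_mult_log2 else 1
    mu[, j] <- lib_factors[j] * bmul * baseline * 2^eff
  }
  counts <- matrix(rnbinom(G * n, mu = mu, size = 1 / dispersion), G, n,
                   dimnames = list(gene_ids, sample_ids))

  samples <- tibble::tibble(sample_id = sample_ids,
                            group = base::factor(group_of, levels = groups))
  if (!is.null(cf$batch)) samples$batch <- base::factor(batch_of)
  structure(list(
    counts = counts, samples = samples,
    truth = list(effects = effects,
                 dispersion = setNames(dispersion, gene_ids),
                 baseline_mean = setNames(baseline, gene_ids),
                 sparse = setNames(sparse, gene_ids),
                 lib_factors = setNames(lib_factors, sample_ids),
                 batch = setNames(batch_of, sample_ids),
                 batch_multiplier_log2 = setNames(batch_mult_log2, gene_ids)),
    config = cf), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples; groups: ",
      paste(names(x$config$group_sizes), x$config$group_sizes,
            sep = "=", collapse = ", "),
      if (!is.null(x$config$batch)) paste0("; hidden batches: ", x$config$batch$n_batches),
      "; seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to counts/metadata/truth files
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.csv"))
  write_counts(sim$counts, paths[["counts"]])
  meta <- as.data.frame(sim$samples)
  utils::write.csv(meta, paths[["metadata"]], row.names = FALSE, quote = FALSE)
  truth <- data.frame(gene = rownames(sim$counts),
                      sim$truth$effects, check.names = FALSE)
  truth$dispersion <- unname(sim$truth$dispersion)
  truth$baseline_mean <- unname(sim$truth$baseline_mean)
  truth$sparse <- unname(sim$truth$sparse)
  write_table_csv(truth, paths[["truth"]])
  invisible(paths)
}
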