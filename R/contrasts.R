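#' Enumerate all ordered contrasts for a factor
#'
#' All k(k-1) ordered (test, reference) pairs for k levels, grouped by
#' reference level: references in level order, and within each reference the
#' test levels in level order. The string form is `"Test-Reference"` with LFC
#' semantics log2(test/reference).
#'
#' @param levels Character vector of distinct group levels, in order.
#' @return A tibble with columns `test`, `reference`, `contrast`.
#' @export
#' @examples
#' enumerate_contrasts(c("Ctrl", "Mild", "Severe"))
enumerate_contrasts <- function(levels) {
  levels <- as.character(levels)
  if (length(levels) < 2) abort("Need at least 2 levels.")
  if (anyDuplicated(levels)) {
    abort(paste0("Duplicate level: '", levels[duplicated(levels)][1], "'."))
  }
  tidyr::expand_grid(reference = levels, test = levels) |>
    dplyr::filter(.data$test != .data$reference) |>
    dplyr::mutate(contrast = paste0(.data$test, "-", .data$reference)) |>
    dplyr::select("test", "reference", "contrast")
}

# parse "Test-Reference" back into its pair, given the known levels
parse_contrast <- function(contrast, levels) {
  for (ref in levels) {
    suffix <- paste0("-", ref)
    if (endsWith(contrast, suffix)) {
      test <- substr(contrast, 1, nchar(contrast) - nchar(suffix))
      if (test %in% levels && test != ref) return(c(test = test, reference = ref))
    }
  }
  abort(paste0("Cannot parse contrast '", contrast, "' against levels ",
               paste(levels, collapse = ", "), "."))
}

#' DEG thresholds
#'
#' A gene is a DEG in a contrast iff its adjusted p-value is strictly below
#' `alpha` and its absolute LFC strictly above `lfc_min`; a missing adjusted p
#' excludes the gene. Defaults: adjusted p < .01 and |LFC| > 2.
#'
#' @param alpha Adjusted-p cutoff in (0, 1].
#' @param lfc_min Absolute-LFC cutoff, >= 0.
#' @return A `deg_thresholds` list.
#' @export
deg_thresholds <- function(alpha = 0.01, lfc_min = 2) {
  stopifnot(alpha > 0, alpha <= 1, lfc_min >= 0)
  structure(list(alpha = alpha, lfc_min = lfc_min), class = "deg_thresholds")
}

#' Call DEGs from a contrast result table
#'
#' Applies the strict thresholds of [deg_thresholds()]: included iff `padj`
#' is present and `< alpha` and `|log2FoldChange| > lfc_min`. Direction is the
#' sign of the LFC (+1 up-regulated in the test group, -1 down).
#'
#' @param table A contrast result table.
#' @param thresholds A [deg_thresholds()].
#' @return A `deg_set` tibble with columns `gene, direction, log2FoldChange,
#'   padj, contrast, alpha, lfc_min` (possibly zero rows).
#' @export
call_degs <- function(table, thresholds = deg_thresholds()) {
  stopifnot(inherits(thresholds, "deg_thresholds"))
  out <- tibble::as_tibble(table) |>
    dplyr::filter(!is.na(.data$padj),
                  .data$padj < thresholds$alpha,
                  abs(.data$log2FoldChange) > thresholds$lfc_min) |>
    dplyr::mutate(direction = ifelse(.data$log2FoldChange > 0, 1L, -1L),
                  alpha = thresholds$alpha, lfc_min = thresholds$lfc_min) |>
    dplyr::select("gene", "direction", "log2FoldChange", "padj", "contrast",
                  "alpha", "lfc_min")
  attr(out, "contrast") <- unique(table$contrast)   # survives an empty call
  class(out) <- c("deg_set", class(out))
  out
}

#' Run the engine with every group as the reference in turn
#'
#' The reference-swapping workhorse: for each level of the design factor the
#' engine is fit once with that level as reference, and the result table for
#' every other level is extracted, so every ordered contrast appears exactly
#' once. Dispersions are estimated on the first fit and shared across the
#' reference-swapped refits (the dispersion model does not depend on the
#' parameterization). DEG sets are called at the supplied thresholds.
#'
#' @inheritParams fit_dge
#' @param thresholds A [deg_thresholds()].
#' @return A `contrast_run` list with elements `tables` (named list of result
#'   tables), `degs` (named list of `deg_set`s), `contrasts` (the enumeration
#'   tibble), `fits` (one `dge_fit` per reference level), `thresholds`,
#'   `config`.
#' @export
run_all_contrasts <- function(counts, samples, factor, covariates = NULL,
                              config = engine_config(),
                              thresholds = deg_thresholds()) {
  counts <- assert_count_matrix(counts)
  samples <- align_samples(counts, samples)
  fac <- as.factor(samples[[factor]])
  lv <- levels(fac)[levels(fac) %in% unique(as.character(fac))]
  plan <- enumerate_contrasts(lv)
  tables <- list(); fits <- list()
  dispersions <- NULL
  prior_sd <- config$prior_sd
  for (ref in lv) {
    fit <- tryCatch(
      fit_dge(counts, samples, factor, ref, covariates, config, dispersions),
      error = function(e) {
        abort(paste0("Engine failed for reference level '", ref, "': ",
                     conditionMessage(e)))
      })
    if (is.null(dispersions)) {
      dispersions <- fit$dispersions
      # the prior scale is a property of the dataset: resolve "auto" once,
      # from the first fit's full set of pairwise contrasts, and share it
      # across the reference-swapped refits
      if (config$mode == "ridge" && identical(prior_sd, "auto")) {
        prior_sd <- estimate_prior_sd(fit)
      }
    }
    if (config$mode == "ridge") fit <- shrink_fit(fit, prior_sd)
    for (tl in fit$test_levels) {
      tables[[paste0(tl, "-", ref)]] <- contrast_results(fit, tl)
    }
    fits[[ref]] <- fit
  }
  tables <- tables[plan$contrast]
  # a gene whose fit fails under any reference parameterization (e.g. one
  # group with all-zero counts sends a coefficient to -Inf in the fits that
  # involve it) is excluded from every contrast of the run: per-fit flags
  # alone would give an asymmetric missingness pattern across reciprocal
  # contrasts and manufacture discordance where the model simply broke
  na_genes <- Reduce(union, lapply(tables, function(t) t$gene[is.na(t$pvalue)]))
  if (length(na_genes) > 0) {
    tables <- lapply(tables, function(t) {
      t$pvalue[t$gene %in% na_genes] <- NA_real_
      t$padj <- bh_adjust(t$pvalue)
      t
    })
  }
  degs <- lapply(tables, call_degs, thresholds = thresholds)
  structure(list(tables = tables, degs = degs, contrasts = plan,
                 fits = fits, thresholds = thresholds, config = config,
                 factor = factor, levels = lv),
            class = "contrast_run")
}

#' @export
print.contrast_run <- function(x, ...) {
  cat("<contrast_run> factor '", x$factor, "', ", length(x$levels),
      " levels -> ", length(x$tables), " ordered contrasts (mode '",
      x$config$mode, "')\n", sep = "")
  n <- vapply(x$degs, nrow, integer(1))
  cat("DEGs per contrast (padj < ", x$thresholds$alpha, ", |LFC| > ",
      x$thresholds$lfc_min, "):\n", sep = "")
  print(n)
  invisible(x)
}

#' All reciprocal pairs of a contrast run
#'
#' @param run A `contrast_run` (or a character vector of `"Test-Reference"`
#'   contrast names plus `levels`).
#' @return Tibble with columns `a`, `b`, `forward`, `reverse`: one row per
#'   unordered pair, the forward direction having the alphabetically later
#'   level as test.
#' @export
reciprocal_pairs <- function(run) {
  lv <- run$levels
  pairs <- utils::combn(sort(lv), 2)
  tibble::tibble(
    a = pairs[2, ], b = pairs[1, ],
    forward = paste0(pairs[2, ], "-", pairs[1, ]),
    reverse = paste0(pairs[1, ], "-", pairs[2, ]))
}
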