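#' Diagnostic plots
#'
#' ggplot2 builders for the toolkit's diagnostics. Every number printed on a
#' plot is computed from the same tabular statistics the other functions
#' return, and is echoed in the `annotations` of the [render()] artifact so it
#' can be checked against them.
#'
#' @param table A contrast result table.
#' @param thresholds A [deg_thresholds()] used to color DEG points and compute
#'   the up/down annotation counts.
#' @return A ggplot object.
#' @name diagnostic_plots
NULL

deg_status <- function(table, thresholds) {
  degs <- call_degs(table, thresholds)
  dplyr::mutate(tibble::as_tibble(table),
                status = dplyr::case_when(
                  .data$gene %in% degs$gene[degs$direction > 0] ~ "up",
                  .data$gene %in% degs$gene[degs$direction < 0] ~ "down",
                  TRUE ~ "ns"))
}

#' @rdname diagnostic_plots
#' @export
plot_volcano <- function(table, thresholds = deg_thresholds()) {
  dat <- deg_status(table, thresholds) |>
    dplyr::filter(!is.na(.data$padj)) |>
    dplyr::mutate(neglog10_padj = -log10(pmax(.data$padj, 1e-300)))
  n_up <- sum(dat$status == "up"); n_down <- sum(dat$status == "down")
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2FoldChange, .data$neglog10_padj,
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70"), drop = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thresholds$alpha), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thresholds$lfc_min,
                        linetype = 2, linewidth = 0.3) +
    ggplot2::annotate("label", x = Inf, y = Inf, hjust = 1.05, vjust = 1.2,
                      label = paste0("up: ", n_up, "\ndown: ", n_down)) +
    ggplot2::labs(title = unique(table$contrast),
                  x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @rdname diagnostic_plots
#' @export
plot_ma <- function(table, thresholds = deg_thresholds()) {
  dat <- deg_status(table, thresholds)
  ggplot2::ggplot(dat, ggplot2::aes(log10(pmax(.data$baseMean, 1e-3)),
                                    .data$log2FoldChange,
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70"), drop = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(title = unique(table$contrast),
                  x = "log10 mean of normalized counts",
                  y = "log2 fold change", colour = NULL) +
    ggplot2::theme_bw()
}

#' Venn diagram of one reciprocal DEG pair
#'
#' Two-set Venn as annotated circles: the forward-only, shared (concordant)
#' and reverse-only counts.
#'
#' @param report A `mirror_report`.
#' @return A ggplot object.
#' @export
plot_venn <- function(report) {
  circ <- function(cx, r = 1.2, n = 200) {
    th <- seq(0, 2 * pi, length.out = n)
    tibble::tibble(x = cx + r * cos(th), y = r * sin(th))
  }
  counts <- c(length(report$discordant_fwd), length(report$concordant),
              length(report$discordant_rev))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circ(-0.7), ggplot2::aes(.data$x, .data$y),
                       colour = "#c0392b") +
    ggplot2::geom_path(data = circ(0.7), ggplot2::aes(.data$x, .data$y),
                       colour = "#e67e22") +
    ggplot2::annotate("text", x = c(-1.3, 0, 1.3), y = 0,
                      label = counts, size = 6) +
    ggplot2::annotate("text", x = c(-0.9, 0.9), y = 1.45,
                      label = c(report$forward, report$reverse)) +
    ggplot2::coord_fixed() + ggplot2::theme_void() +
    ggplot2::labs(title = paste0("DEG overlap: ", report$forward, " / ",
                                 report$reverse))
}

#' Stacked concordance bars across reciprocal pairs
#'
#' One horizontal bar per pair; the two discordant segments first, the
#' concordant segment last (rightmost, green), so a fully green bar is a pair
#' that passes the mirror check.
#'
#' @param reports A list of `mirror_report`s (as from [mirror_reports()]).
#' @return A ggplot object.
#' @export
plot_stacked_bar <- function(reports) {
  td <- purrr::map_dfr(reports, tidy)
  long <- td |>
    dplyr::mutate(pair = paste0(.data$forward, " / ", .data$reverse)) |>
    tidyr::pivot_longer(c("n_discordant_fwd", "n_discordant_rev", "n_concordant"),
                        names_to = "category", values_to = "n") |>
    dplyr::mutate(category = base::factor(
      .data$category,
      # concordant drawn last = rightmost segment
      levels = c("n_concordant", "n_discordant_rev", "n_discordant_fwd"),
      labels = c("concordant", "discordant (reverse ref)",
                 "discordant (forward ref)")))
  ggplot2::ggplot(long, ggplot2::aes(.data$n, .data$pair, fill = .data$category)) +
    ggplot2::geom_col(position = ggplot2::position_stack()) +
    ggplot2::scale_fill_manual(values = c(
      "concordant" = "#27ae60",
      "discordant (reverse ref)" = "#e67e22",
      "discordant (forward ref)" = "#c0392b")) +
    ggplot2::labs(x = "DEGs", y = NULL, fill = NULL,
                  title = "Reciprocal-contrast concordance") +
    ggplot2::theme_bw()
}

#' Density of reciprocal LFC sums for concordant DEGs
#'
#' Deviation of `LFC_fwd + LFC_rev` from 0 across concordant genes; a spike
#' at 0 means stable shrinkage, spread means reference dependence.
#'
#' @param sums The `sums` tibble from [lfc_mirror_sums()] (or the whole list).
#' @param label Optional contrast-pair label for the title.
#' @return A ggplot object.
#' @export
plot_lfc_density <- function(sums, label = NULL) {
  if (is.list(sums) && !is.data.frame(sums)) sums <- sums$sums
  p <- ggplot2::ggplot(sums, ggplot2::aes(.data$lfc_sum)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "LFC(fwd) + LFC(rev)", y = "density",
                  title = label %||% "Concordant DEG LFC sums") +
    ggplot2::theme_bw()
  if (nrow(sums) >= 2 && sd(sums$lfc_sum) > 0) {
    p <- p + ggplot2::geom_density(fill = "#27ae60", alpha = 0.4)
  } else if (nrow(sums) >= 1) {
    p <- p + ggplot2::geom_histogram(bins = 30, fill = "#27ae60", alpha = 0.6)
  }
  p
}

#' UpSet plot of exclusive intersections
#'
#' Bars of the exclusive intersection sizes over a dot matrix of set
#' membership, assembled with patchwork.
#'
#' @param itab An `intersection_table` from [compute_intersections()].
#' @param n_max Show at most this many intersections (largest first).
#' @return A patchwork object.
#' @export
plot_upset <- function(itab, n_max = 20) {
  sets <- attr(itab, "set_names")
  top <- head(itab, n_max) |>
    dplyr::mutate(ix = factor(seq_len(dplyr::n())))
  bars <- ggplot2::ggplot(top, ggplot2::aes(.data$ix, .data$size)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$size), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "exclusive size") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
  dots <- top |>
    dplyr::mutate(members = strsplit(.data$intersection, "&", fixed = TRUE)) |>
    dplyr::select("ix", "members") |>
    tidyr::unnest_longer("members") |>
    dplyr::mutate(set = base::factor(.data$members, levels = rev(sets)))
  grid <- tidyr::expand_grid(ix = top$ix, set = base::factor(sets, levels = rev(sets)))
  matrix_p <- ggplot2::ggplot(grid, ggplot2::aes(.data$ix, .data$set)) +
    ggplot2::geom_point(colour = "grey85", size = 2.5) +
    ggplot2::geom_point(data = dots, colour = "grey15", size = 2.5) +
    ggplot2::geom_line(data = dots, ggplot2::aes(group = .data$ix), colour = "grey15") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
  patchwork::wrap_plots(bars, matrix_p, ncol = 1, heights = c(2, 1))
}

#' Heatmap of DEG expression
#'
#' Per-gene z-scored log2(normalized count + 1) for the supplied genes,
#' samples grouped by factor level, no clustering.
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample metadata.
#' @param factor Grouping column name.
#' @param genes Character vector of gene IDs (e.g. concordant DEGs).
#' @return A ggplot object.
#' @export
plot_deg_heatmap <- function(counts, samples, factor, genes) {
  counts <- assert_count_matrix(counts)
  samples <- align_samples(counts, samples)
  genes <- intersect(genes, rownames(counts))
  ord <- order(samples[[factor]])
  if (length(genes) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "0 DEGs") +
             ggplot2::theme_void())
  }
  sf <- estimate_size_factors(counts)
  expr <- log2(sweep(counts[genes, , drop = FALSE], 2, sf, "/") + 1)
  z <- t(scale(t(expr)))
  z[is.nan(z)] <- 0
  long <- tibble::as_tibble(z, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "z") |>
    dplyr::mutate(sample_id = base::factor(.data$sample_id,
                                           levels = samples$sample_id[ord]),
                  gene = base::factor(.data$gene, levels = rev(genes)))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$gene, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white", high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' PCA overview of a dataset
#'
#' Principal components of log2(normalized count + 1) over the top
#' `ntop`-variance genes (a simple pinned transform in place of a
#' variance-stabilizing one), samples colored by group.
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample metadata.
#' @param factor Grouping column name.
#' @param ntop Number of top-variance genes (default 500).
#' @return A ggplot object; the per-component variance shares (percent) are
#'   attached as attribute `variance_pct`.
#' @export
plot_pca <- function(counts, samples, factor, ntop = 500) {
  counts <- assert_count_matrix(counts)
  samples <- align_samples(counts, samples)
  sf <- estimate_size_factors(counts)
  expr <- log2(sweep(counts, 2, sf, "/") + 1)
  rv <- apply(expr, 1, var)
  sel <- head(order(rv, decreasing = TRUE), min(ntop, nrow(expr)))
  pc <- prcomp(t(expr[sel, , drop = FALSE]), center = TRUE, scale. = FALSE)
  share <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  dat <- tibble::tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                        group = samples[[factor]])
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$PC1, .data$PC2,
                                         colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", share[1]),
                  y = sprintf("PC2 (%.0f%%)", share[2]), colour = factor) +
    ggplot2::theme_bw()
  attr(p, "variance_pct") <- share
  p
}

#' Render a diagnostic plot to a file
#'
#' Builds the plot for `kind` from `data` and writes a PNG, returning a
#' `plot_artifact` whose `annotations` echo every number printed on the plot
#' (up/down DEG counts, category sizes, variance shares, ...) so they can be
#' asserted against the tabular outputs.
#'
#' @param kind One of `"volcano"`, `"ma"`, `"venn"`, `"stacked_bar"`,
#'   `"density"`, `"upset"`, `"heatmap"`, `"pca"`.
#' @param data The matching input: a contrast result table (volcano/ma), a
#'   `mirror_report` (venn), a list of them (stacked_bar), an
#'   [lfc_mirror_sums()] result (density), an `intersection_table` (upset), a
#'   list `list(counts, samples, factor, genes)` (heatmap), or
#'   `list(counts, samples, factor)` (pca).
#' @param thresholds A [deg_thresholds()] (volcano/ma only).
#' @param outpath Output file path (PNG).
#' @param width,height Device size in inches.
#' @return A `plot_artifact`: list with `kind`, `path`, `annotations`, `plot`.
#' @export
render <- function(kind, data, thresholds = deg_thresholds(), outpath,
                   width = 6, height = 5) {
  kind <- match.arg(kind, c("volcano", "ma", "venn", "stacked_bar", "density",
                            "upset", "heatmap", "pca"))
  ann <- list()
  p <- switch(kind,
    volcano = {
      degs <- call_degs(data, thresholds)
      ann <- list(n_up = sum(degs$direction > 0),
                  n_down = sum(degs$direction < 0))
      plot_volcano(data, thresholds)
    },
    ma = {
      degs <- call_degs(data, thresholds)
      ann <- list(n_up = sum(degs$direction > 0),
                  n_down = sum(degs$direction < 0))
      plot_ma(data, thresholds)
    },
    venn = {
      ann <- list(n_fwd_only = length(data$discordant_fwd),
                  n_concordant = length(data$concordant),
                  n_rev_only = length(data$discordant_rev))
      plot_venn(data)
    },
    stacked_bar = {
      td <- purrr::map_dfr(data, tidy)
      ann <- list(segments = td[, c("forward", "n_discordant_fwd",
                                    "n_discordant_rev", "n_concordant")])
      plot_stacked_bar(data)
    },
    density = {
      s <- if (is.data.frame(data)) data else data$sums
      ann <- list(n = nrow(s),
                  mean = if (nrow(s)) mean(s$lfc_sum) else NA_real_,
                  max_abs = if (nrow(s)) max(abs(s$lfc_sum)) else NA_real_)
      plot_lfc_density(data)
    },
    upset = {
      ann <- list(sizes = setNames(data$size, data$intersection))
      plot_upset(data)
    },
    heatmap = {
      ann <- list(n_genes = length(intersect(data$genes, rownames(data$counts))))
      plot_deg_heatmap(data$counts, data$samples, data$factor, data$genes)
    },
    pca = {
      pp <- plot_pca(data$counts, data$samples, data$factor,
                     ntop = data$ntop %||% 500)
      ann <- list(variance_pct = attr(pp, "variance_pct"))
      pp
    })
  ggplot2::ggsave(outpath, p, width = width, height = height, dpi = 150)
  structure(list(kind = kind, path = outpath, annotations = ann, plot = p),
            class = "plot_artifact")
}

#' @export
print.plot_artifact <- function(x, ...) {
  cat("<plot_artifact> ", x$kind, " -> ", x$path, "\n", sep = "")
  utils::str(x$annotations, max.level = 1)
  invisible(x)
}

# --- autoplot / tidiers -------------------------------------------------------

#' Autoplot methods
#'
#' `autoplot()` on a `mirror_report` draws its Venn diagram, on an
#' `intersection_table` the UpSet plot, on a `sim_dataset` the PCA overview,
#' and on a `dge_fit` the per-gene dispersion against mean with the fitted
#' trend moderation visible.
#'
#' @param object The object to plot.
#' @param ... Passed through where meaningful.
#' @return A ggplot (or patchwork) object.
#' @name autoplot_methods
NULL

#' @rdname autoplot_methods
#' @method autoplot mirror_report
#' @export
autoplot.mirror_report <- function(object, ...) plot_venn(object)

#' @rdname autoplot_methods
#' @method autoplot intersection_table
#' @export
autoplot.intersection_table <- function(object, ...) plot_upset(object, ...)

#' @rdname autoplot_methods
#' @method autoplot sim_dataset
#' @export
autoplot.sim_dataset <- function(object, factor = "group", ...) {
  plot_pca(object$counts, object$samples, factor, ...)
}

#' @rdname autoplot_methods
#' @method autoplot dge_fit
#' @export
autoplot.dge_fit <- function(object, ...) {
  dat <- tibble::tibble(baseMean = object$base_mean,
                        genewise = object$dispersions_genewise,
                        final = object$dispersions) |>
    dplyr::filter(.data$baseMean > 0, !is.na(.data$final))
  ggplot2::ggplot(dat, ggplot2::aes(log10(.data$baseMean))) +
    ggplot2::geom_point(ggplot2::aes(y = log10(pmax(.data$genewise, 1e-8))),
                        size = 0.6, alpha = 0.4, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = log10(.data$final)), size = 0.6,
                        alpha = 0.5, colour = "#2980b9") +
    ggplot2::labs(x = "log10 baseMean", y = "log10 dispersion",
                  title = "Gene-wise (grey) and trend-moderated (blue) dispersion") +
    ggplot2::theme_bw()
}

#' Tidy / glance methods for fitted engines
#'
#' `tidy()` returns the per-gene coefficient table of one fit (one row per
#' gene and non-reference level, log2 scale); `glance()` a one-row fit
#' summary.
#'
#' @param x A `dge_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dge_fit
#' @export
tidy.dge_fit <- function(x, ...) {
  purrr::map_dfr(x$test_levels, function(tl) contrast_results(x, tl, mode = "none"))
}

#' @rdname tidy.dge_fit
#' @method glance dge_fit
#' @export
glance.dge_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$counts), n_samples = ncol(x$counts),
    factor = x$factor, reference = x$reference,
    n_levels = length(x$levels),
    n_covariates = length(x$covariates),
    n_converged = sum(x$converged),
    n_flagged = sum(x$nonzero & !x$converged),
    n_zero = sum(!x$nonzero),
    mode = x$config$mode)
}
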