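#' Classify concordant and discordant DEGs for a reciprocal pair
#'
#' A DEG is *concordant* if it appears in both reciprocal DEG lists (matching
#' the membership-based definition: observed in both reciprocal contrasts),
#' *discordant* if it appears only under one choice of reference. Concordance
#' is defined by membership, not sign opposition; concordant genes whose two
#' directions are not opposite are counted separately as sign violations and
#' surfaced with a warning, since the LFC-sum density is the instrument that
#' detects them.
#'
#' @param fwd,rev `deg_set`s for a reciprocal pair of contrasts, called at
#'   identical thresholds. An empty set is valid.
#' @param forward,reverse Optional explicit contrast labels (needed only when
#'   a set is empty and carries no label of its own).
#' @return A `mirror_report` list: `pair`, `forward`, `reverse`, `concordant`,
#'   `discordant_fwd`, `discordant_rev` (character vectors of gene IDs),
#'   `sign_violations`, `discordance_pct`, and a `genes` tibble with one row
#'   per union gene and its category.
#' @export
classify_concordance <- function(fwd, rev, forward = NULL, reverse = NULL) {
  for (d in list(fwd, rev)) {
    stopifnot(all(c("gene", "direction", "contrast", "alpha", "lfc_min") %in% names(d)))
  }
  label_of <- function(d, explicit) {
    lb <- explicit %||%
      (if (nrow(d) > 0) unique(d$contrast) else attr(d, "contrast", exact = TRUE))
    if (length(lb) > 1) abort("Each DEG set must be one contrast.")
    lb
  }
  fc <- label_of(fwd, forward); rc <- label_of(rev, reverse)
  if (is.null(fc) || is.null(rc)) {
    abort("Cannot determine the contrast of an empty DEG set; pass `forward`/`reverse`.")
  }
  fwd_pair <- strsplit_contrast(fc, rc)
  a_f <- tolerant_thresholds(fwd); a_r <- tolerant_thresholds(rev)
  if (!is.null(a_f) && !is.null(a_r) && !isTRUE(all.equal(a_f, a_r))) {
    abort("Reciprocal DEG sets were called at different thresholds.")
  }
  concordant <- sort(intersect(fwd$gene, rev$gene))
  discordant_fwd <- sort(setdiff(fwd$gene, rev$gene))
  discordant_rev <- sort(setdiff(rev$gene, fwd$gene))
  dir_f <- setNames(fwd$direction, fwd$gene)
  dir_r <- setNames(rev$direction, rev$gene)
  sign_violations <- concordant[dir_f[concordant] == dir_r[concordant]]
  if (length(sign_violations) > 0) {
    warn(paste0(length(sign_violations),
                " concordant gene(s) do not have opposite directions in the two contrasts."))
  }
  genes <- dplyr::bind_rows(
    tibble::tibble(gene = concordant, category = "concordant"),
    tibble::tibble(gene = discordant_fwd, category = "discordant_fwd"),
    tibble::tibble(gene = discordant_rev, category = "discordant_rev"))
  rep <- structure(list(
    pair = sort(fwd_pair), forward = fc, reverse = rc,
    concordant = concordant, discordant_fwd = discordant_fwd,
    discordant_rev = discordant_rev, sign_violations = sign_violations,
    thresholds = a_f %||% a_r, genes = genes), class = "mirror_report")
  rep$discordance_pct <- discordance_pct(rep)
  rep
}

tolerant_thresholds <- function(d) {
  if (nrow(d) == 0) return(NULL)
  list(alpha = unique(d$alpha), lfc_min = unique(d$lfc_min))
}

# check the two contrast strings are reversals of each other and return the
# unordered level pair
strsplit_contrast <- function(fc, rc) {
  if (length(fc) == 0 || length(rc) == 0 || is.na(fc) || is.na(rc)) {
    abort("Both DEG sets must carry a contrast label.")
  }
  # "T-R" reversed is "R-T"; split on every "-" position and find a reading
  # under which the two agree
  pos_f <- gregexpr("-", fc, fixed = TRUE)[[1]]
  for (p in pos_f) {
    test <- substr(fc, 1, p - 1); ref <- substr(fc, p + 1, nchar(fc))
    if (paste0(ref, "-", test) == rc) return(c(test, ref))
  }
  abort(paste0("Contrasts '", fc, "' and '", rc, "' are not reciprocal."))
}

#' @export
print.mirror_report <- function(x, ...) {
  cat("<mirror_report> ", x$forward, " vs ", x$reverse, "\n", sep = "")
  cat("  concordant: ", length(x$concordant),
      "; discordant (", x$forward, " only): ", length(x$discordant_fwd),
      "; discordant (", x$reverse, " only): ", length(x$discordant_rev), "\n", sep = "")
  cat("  discordance: ", sprintf("%.2f", x$discordance_pct), "%",
      if (length(x$sign_violations)) paste0("; sign violations: ", length(x$sign_violations)),
      "\n", sep = "")
  invisible(x)
}

#' Discordance percentage of a reciprocal pair
#'
#' 100 minus the percentage of the DEG union that is concordant:
#' `100 - 100 * concordant / (concordant + discordant_fwd + discordant_rev)`,
#' pinned to 0 when the union is empty.
#'
#' @param report A `mirror_report`, or a list with `concordant`,
#'   `discordant_fwd`, `discordant_rev` gene vectors (or counts).
#' @return A number in `[0, 100]`.
#' @export
#' @examples
#' discordance_pct(list(concordant = 8, discordant_fwd = 2, discordant_rev = 0)) # 20
discordance_pct <- function(report) {
  n <- vapply(report[c("concordant", "discordant_fwd", "discordant_rev")],
              function(x) if (is.numeric(x) && length(x) == 1) x else length(x),
              numeric(1))
  total <- sum(n)
  if (total == 0) return(0)
  100 - 100 * n[["concordant"]] / total
}

#' Percentage change in concordant DEG count after data cleaning
#'
#' `100 * (after - before) / before`; undefined (NA, with attribute
#' `undefined`) when `before` is 0.
#'
#' @param before,after Nonnegative concordant DEG counts without / with the
#'   cleaning step.
#' @return A number, or flagged `NA` when `before == 0`.
#' @export
#' @examples
#' pct_change_concordant(100, 125) # +25
pct_change_concordant <- function(before, after) {
  stopifnot(before >= 0, after >= 0)
  if (before == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  100 * (after - before) / before
}

#' Per-gene sums of reciprocal LFCs for concordant DEGs
#'
#' For each concordant gene, `LFC_fwd + LFC_rev`: 0 under exact mirroring,
#' deviating from 0 exactly where shrinkage is reference-dependent. The
#' summary (mean, sd, max absolute) quantifies the deviation per pair; the
#' per-gene values feed the density diagnostic plot.
#'
#' @param fwd_table,rev_table Full contrast result tables for the pair.
#' @param concordant Character vector of concordant gene IDs.
#' @return A list with `sums` (tibble gene/lfc_fwd/lfc_rev/lfc_sum) and
#'   `summary` (tibble mean/sd/max_abs/n).
#' @export
lfc_mirror_sums <- function(fwd_table, rev_table, concordant) {
  f <- setNames(fwd_table$log2FoldChange, fwd_table$gene)
  r <- setNames(rev_table$log2FoldChange, rev_table$gene)
  missing <- setdiff(concordant, intersect(names(f)[!is.na(f)], names(r)[!is.na(r)]))
  if (length(missing) > 0) {
    abort(paste0("Concordant gene(s) missing from a result table: ",
                 paste(head(missing, 5), collapse = ", "), "."))
  }
  sums <- tibble::tibble(
    gene = concordant,
    lfc_fwd = unname(f[concordant]),
    lfc_rev = unname(r[concordant]),
    lfc_sum = unname(f[concordant] + r[concordant]))
  summary <- tibble::tibble(
    n = nrow(sums),
    mean = if (nrow(sums)) mean(sums$lfc_sum) else NA_real_,
    sd = if (nrow(sums) > 1) sd(sums$lfc_sum) else NA_real_,
    max_abs = if (nrow(sums)) max(abs(sums$lfc_sum)) else NA_real_)
  list(sums = sums, summary = summary)
}

#' Expression-split diagnostic for a reciprocal pair
#'
#' Tests whether discordant DEGs sit at lower expression than concordant ones:
#' log10(baseMean) per gene, grouped by category (concordant, discordant under
#' each reference), with a global Kruskal-Wallis p and uncorrected pairwise
#' Wilcoxon rank-sum p-values for every pair of nonempty categories (matching
#' the per-pair annotation convention of the diagnostic figure).
#'
#' @param report A `mirror_report`.
#' @param base_means Named numeric vector of baseMean per gene (reference- and
#'   contrast-invariant, so either table of the pair works).
#' @return A list: `data` (tibble gene/category/log10_baseMean), `global_p`
#'   (Kruskal-Wallis; NA when fewer than 2 categories are nonempty),
#'   `pairwise` (tibble category pairs with Wilcoxon p, skipped pairs absent).
#' @export
expression_split_test <- function(report, base_means) {
  dat <- report$genes
  missing <- setdiff(dat$gene, names(base_means))
  if (length(missing) > 0) {
    abort(paste0("baseMean missing for gene(s): ",
                 paste(head(missing, 5), collapse = ", "), "."))
  }
  dat <- dplyr::mutate(dat, log10_baseMean = log10(pmax(base_means[.data$gene], 1e-12)))
  cats <- dat |> dplyr::count(.data$category) |> dplyr::filter(.data$n > 0)
  if (nrow(cats) < 2) {
    return(list(data = dat, global_p = structure(NA_real_, undefined = TRUE),
                pairwise = tibble::tibble(cat1 = character(), cat2 = character(),
                                          p = numeric())))
  }
  global_p <- kruskal.test(log10_baseMean ~ factor(category), data = dat)$p.value
  cmb <- utils::combn(sort(cats$category), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
    x <- dat$log10_baseMean[dat$category == cmb[1, i]]
    y <- dat$log10_baseMean[dat$category == cmb[2, i]]
    tibble::tibble(cat1 = cmb[1, i], cat2 = cmb[2, i],
                   p = suppressWarnings(wilcox.test(x, y)$p.value))
  })
  list(data = dat, global_p = global_p, pairwise = pairwise)
}

#' Exclusive (UpSet-style) intersections of named gene sets
#'
#' Partitions the union of the supplied sets into exclusive intersections:
#' every gene lands in exactly one membership pattern, so the exclusive sizes
#' sum to the union size. Rows are ordered by size descending, ties by
#' intersection name.
#'
#' @param sets Named list of character vectors (or `deg_set`s, whose `gene`
#'   columns are used). At least two, uniquely named.
#' @return An `intersection_table` tibble with columns `intersection` (set
#'   names joined by `&`), `degree`, `size`, `genes` (list column), plus a
#'   `membership` attribute tibble (gene x set logicals) for export/plotting.
#' @export
compute_intersections <- function(sets) {
  if (length(sets) < 2) abort("Need at least 2 sets.")
  if (is.null(names(sets)) || any(names(sets) == "") || anyDuplicated(names(sets))) {
    abort("Sets must be uniquely named.")
  }
  sets <- lapply(sets, function(s) {
    if (is.data.frame(s)) s <- s$gene
    unique(as.character(s))
  })
  universe <- sort(unique(unlist(sets)))
  membership <- tibble::tibble(gene = universe)
  for (nm in names(sets)) membership[[nm]] <- universe %in% sets[[nm]]
  if (length(universe) == 0) {
    out <- tibble::tibble(intersection = character(), degree = integer(),
                          size = integer(), genes = list())
  } else {
    pattern <- apply(as.matrix(membership[, names(sets), drop = FALSE]), 1,
                     function(m) paste(names(sets)[m], collapse = "&"))
    out <- tibble::tibble(gene = universe, intersection = pattern) |>
      dplyr::group_by(.data$intersection) |>
      dplyr::summarise(size = dplyr::n(), genes = list(sort(.data$gene)),
                       .groups = "drop") |>
      dplyr::mutate(degree = lengths(strsplit(.data$intersection, "&", fixed = TRUE))) |>
      dplyr::arrange(dplyr::desc(.data$size), .data$intersection) |>
      dplyr::select("intersection", "degree", "size", "genes")
  }
  attr(out, "membership") <- membership
  attr(out, "set_names") <- names(sets)
  class(out) <- c("intersection_table", class(out))
  out
}

#' Write the intersection detail CSV
#'
#' One gene per row: its exclusive intersection label and one logical column
#' per input set.
#'
#' @param itab An `intersection_table` from [compute_intersections()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_intersections_csv <- function(itab, path) {
  membership <- attr(itab, "membership")
  detail <- itab |>
    dplyr::select("intersection", "genes") |>
    tidyr::unnest_longer("genes", values_to = "gene") |>
    dplyr::left_join(membership, by = "gene") |>
    dplyr::select("gene", "intersection", dplyr::everything())
  utils::write.csv(as.data.frame(detail), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tidy a mirror report
#'
#' @param x A `mirror_report`.
#' @param ... Unused.
#' @return One-row tibble of pair, counts per category, discordance
#'   percentage and sign-violation count.
#' @method tidy mirror_report
#' @export
tidy.mirror_report <- function(x, ...) {
  tibble::tibble(
    forward = x$forward, reverse = x$reverse,
    n_concordant = length(x$concordant),
    n_discordant_fwd = length(x$discordant_fwd),
    n_discordant_rev = length(x$discordant_rev),
    n_union = length(x$concordant) + length(x$discordant_fwd) +
      length(x$discordant_rev),
    discordance_pct = x$discordance_pct,
    n_sign_violations = length(x$sign_violations))
}

#' Mirror reports for every reciprocal pair of a contrast run
#'
#' The forward direction of each pair takes the alphabetically later level as
#' test (override by supplying your own pair table).
#'
#' @param run A `contrast_run` from [run_all_contrasts()].
#' @param pairs Optional pair tibble as from [reciprocal_pairs()].
#' @return Named list of `mirror_report`s (one per unordered pair, named
#'   `"A|B"`).
#' @export
mirror_reports <- function(run, pairs = reciprocal_pairs(run)) {
  reps <- purrr::pmap(pairs, function(a, b, forward, reverse) {
    classify_concordance(run$degs[[forward]], run$degs[[reverse]],
                         forward = forward, reverse = reverse)
  })
  names(reps) <- paste0(pairs$a, "|", pairs$b)
  reps
}
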