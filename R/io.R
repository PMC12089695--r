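#' Read a gene-by-sample counts table
#'
#' Reads a counts matrix from TSV/CSV (genes in rows, a header row of sample
#' IDs, first column gene IDs) or from a MatrixMarket triplet file accompanied
#' by sidecar row/column name files. Values within 1e-6 of an integer are
#' rounded; anything else is rejected, as are negative values and duplicate
#' IDs.
#'
#' @param path Path to the counts file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Defaults from the file
#'   extension.
#' @param row_names,col_names For `format = "mtx"`: paths to one-ID-per-line
#'   files giving gene and sample IDs. Default to `<path>.rownames` /
#'   `<path>.colnames`.
#' @return A numeric matrix of nonnegative integers with gene IDs as rownames
#'   and sample IDs as colnames.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' write_counts(m, tf)
#' identical(read_counts(tf), m * 1.0)
read_counts <- function(path, format = NULL,
                        row_names = NULL, col_names = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               csv = "csv", mtx = "mtx", "tsv")
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    row_names <- row_names %||% paste0(path, ".rownames")
    col_names <- col_names %||% paste0(path, ".colnames")
    rownames(m) <- readLines(row_names)
    colnames(m) <- readLines(col_names)
    return(assert_count_matrix(m))
  }
  delim <- if (format == "csv") "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort(paste0("Counts file is empty or has no sample columns: ", path))
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("Counts columns must be numeric.")
  rownames(m) <- ids
  assert_count_matrix(m)
}

#' Write a counts matrix
#'
#' Inverse of [read_counts()] for the TSV/CSV dialect; `read_counts()` on the
#' written file reproduces the matrix exactly.
#'
#' @param counts Gene-by-sample integer matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  counts <- assert_count_matrix(counts)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  delim <- if (format == "csv") "," else "\t"
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads sample metadata (CSV/TSV, one row per sample) and records the design
#' factor's levels in first-appearance order unless an explicit order is given.
#' A factor level with fewer than 2 samples triggers a warning here and a hard
#' error only at model-fit time.
#'
#' @param path Path to the metadata file.
#' @param factor Name of the grouping column.
#' @param sample_col Name of the sample-ID column (default `"sample_id"`, or
#'   the first column if that name is absent).
#' @param levels Optional explicit level order for the factor.
#' @return A tibble with `sample_id`, the factor column (as a factor), and any
#'   remaining covariate columns.
#' @export
read_metadata <- function(path, factor, sample_col = "sample_id",
                          levels = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (!sample_col %in% names(df)) sample_col <- names(df)[1]
  if (!factor %in% names(df)) {
    abort(paste0("Factor column '", factor, "' not found. Available columns: ",
                 paste(setdiff(names(df), sample_col), collapse = ", "), "."))
  }
  df <- dplyr::rename(df, sample_id = dplyr::all_of(sample_col))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("Duplicate sample_id in metadata: '",
                 df$sample_id[duplicated(df$sample_id)][1], "'."))
  }
  lv <- levels %||% unique(as.character(df[[factor]]))
  if (!all(as.character(df[[factor]]) %in% lv)) {
    abort("Supplied `levels` do not cover all observed factor values.")
  }
  df[[factor]] <- base::factor(as.character(df[[factor]]), levels = lv)
  n_per <- table(df[[factor]])
  if (any(n_per < 2)) {
    warn(paste0("Factor level(s) with fewer than 2 samples: ",
                paste(names(n_per)[n_per < 2], collapse = ", "),
                ". Model fitting will fail for these."))
  }
  tibble::as_tibble(df)
}

#' Write a GSEAPreranked .rnk ranked gene list
#'
#' Ranks every gene of a full (unthresholded) contrast result table by its
#' log2 fold change, descending, with LFC ties broken by lexicographic gene
#' ID, and writes the two-column tab-separated, header-free `.rnk` dialect.
#' Genes with a missing LFC are dropped with a message giving the count.
#'
#' @param table A contrast result table (from [contrast_results()]), or any
#'   data frame with `gene` and `log2FoldChange` columns.
#' @param path Output `.rnk` path.
#' @return A tibble of the ranked list (gene, stat), invisibly.
#' @export
write_ranked_list <- function(table, path) {
  stopifnot(all(c("gene", "log2FoldChange") %in% names(table)))
  tab <- tibble::as_tibble(table)[, c("gene", "log2FoldChange")]
  n_na <- sum(is.na(tab$log2FoldChange))
  if (n_na > 0) {
    inform(paste0("Dropping ", n_na, " gene(s) with missing LFC from ranked list."))
    tab <- tab[!is.na(tab$log2FoldChange), ]
  }
  tab <- dplyr::arrange(tab, dplyr::desc(.data$log2FoldChange), .data$gene)
  lines <- paste0(tab$gene, "\t", fmt_num(tab$log2FoldChange))
  writeLines(lines, path)
  invisible(tab)
}

#' Write / read a full contrast result table as CSV
#'
#' Fixed column schema `gene, baseMean, log2FoldChange, lfcSE, pvalue, padj`,
#' full-precision numerics, missing values serialized as `NA`.
#'
#' @param table A contrast result table.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_result_table <- function(table, path) {
  cols <- c("gene", "baseMean", "log2FoldChange", "lfcSE", "pvalue", "padj")
  stopifnot(all(cols %in% names(table)))
  write_table_csv(as.data.frame(table)[, cols], path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE)
}

#' Write / read a DEG list as CSV
#'
#' One gene per row with its direction (+1 up, -1 down in the test group),
#' shrunken LFC and adjusted p, plus the contrast and thresholds echoed so a
#' comparison stage can verify they match.
#'
#' @param degs A DEG set tibble from [call_degs()].
#' @param path CSV path.
#' @return `path` (write) or a DEG set tibble (read).
#' @export
write_deg_csv <- function(degs, path) {
  cols <- c("gene", "direction", "log2FoldChange", "padj",
            "contrast", "alpha", "lfc_min")
  stopifnot(all(cols %in% names(degs)))
  write_table_csv(as.data.frame(degs)[, cols], path)
}

#' @rdname write_deg_csv
#' @export
read_deg_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), contrast = readr::col_character(),
    .default = readr::col_double()), progress = FALSE, show_col_types = FALSE)
  class(df) <- c("deg_set", class(df))
  df
}
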