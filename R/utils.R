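# shared internal helpers

`%||%` <- rlang::`%||%`

# numeric formatting used for every tabular artifact: full-precision %.15g so
# diffs of re-runs are stable across platforms
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1))
  out
}

# write a data frame as CSV with %.15g numerics and "NA" for missing values
write_table_csv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

assert_count_matrix <- function(counts, call = rlang::caller_env()) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (genes x samples).", call = call)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene IDs as rownames and sample IDs as colnames.",
          call = call)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    abort(paste0("Duplicate gene ID in counts: '", dup, "'."), call = call)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    abort(paste0("Duplicate sample ID in counts: '", dup, "'."), call = call)
  }
  if (nrow(counts) < 1 || ncol(counts) < 2) {
    abort("Counts must have at least 1 gene and 2 samples.", call = call)
  }
  if (anyNA(counts)) abort("Counts contain missing values.", call = call)
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(paste0("Negative count for gene '", rownames(counts)[neg[1, 1]],
                 "', sample '", colnames(counts)[neg[1, 2]], "'."), call = call)
  }
  off <- abs(counts - round(counts))
  if (any(off > 1e-6)) {
    bad <- which(off > 1e-6, arr.ind = TRUE)
    abort(paste0("Non-integer count for gene '", rownames(counts)[bad[1, 1]],
                 "', sample '", colnames(counts)[bad[1, 2]], "'."), call = call)
  }
  storage.mode(counts) <- "double"
  round(counts)
}

# align a sample table to the column order of a counts matrix, by sample_id
align_samples <- function(counts, samples, call = rlang::caller_env()) {
  if (!"sample_id" %in% names(samples)) {
    abort("`samples` must contain a 'sample_id' column.", call = call)
  }
  missing_in_counts <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_in_counts) > 0) {
    abort(paste0("Sample(s) in metadata absent from counts: ",
                 paste(missing_in_counts, collapse = ", "), "."), call = call)
  }
  missing_in_meta <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_in_meta) > 0) {
    abort(paste0("Sample(s) in counts absent from metadata: ",
                 paste(missing_in_meta, collapse = ", "), "."), call = call)
  }
  samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
}
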