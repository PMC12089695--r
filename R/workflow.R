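#' Run configuration for the end-to-end workflow
#'
#' Bundles everything one differential-expression run needs; a saved config
#' reruns byte-identically given the same code version.
#'
#' @param counts Path to the counts file (or a counts matrix).
#' @param metadata Path to the metadata file (or a sample tibble).
#' @param factor Design factor column name.
#' @param mode Engine shrinkage mode (see [engine_config()]).
#' @param prior_sd Ridge prior sd (log2 units).
#' @param alpha,lfc_min DEG thresholds (see [deg_thresholds()]).
#' @param cleaning One of `"none"`, `"prefilter"`, `"sva"`, `"both"`.
#' @param print_all Also write the full unthresholded result table (and the
#'   `.rnk` ranked list) per contrast.
#' @param plots Write volcano/MA plots per contrast (default TRUE).
#' @param outdir Output directory.
#' @param seed Seed (used by the surrogate-variable permutation test).
#' @return A `run_config` list.
#' @export
run_config <- function(counts, metadata, factor, mode = "none", prior_sd = 1,
                       alpha = 0.01, lfc_min = 2,
                       cleaning = c("none", "prefilter", "sva", "both"),
                       print_all = FALSE, plots = TRUE, outdir, seed = 1) {
  cleaning <- match.arg(cleaning)
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  if (lfc_min < 0) abort("`lfc_min` must be >= 0.")
  structure(list(counts = counts, metadata = metadata, factor = factor,
                 mode = mode, prior_sd = prior_sd, alpha = alpha,
                 lfc_min = lfc_min, cleaning = cleaning,
                 print_all = isTRUE(print_all), plots = isTRUE(plots),
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  inform(msg)
  if (!is.null(con)) writeLines(paste0(format(Sys.time(), "%H:%M:%S"), " INFO ", msg), con)
}

#' Execute a full differential-expression run into a run directory
#'
#' The run stage of the workflow: load (or accept) counts and metadata, apply
#' the selected cleaning (prefiltering and/or surrogate-variable estimation,
#' the latter adding `SV*` covariates to the design), run the engine with
#' every group as reference in turn, and write per-contrast outputs under
#' `<outdir>/contrasts/<Test-Reference>/` (DEG CSV, optional full results CSV
#' + `.rnk` list, optional volcano/MA PNGs) plus a plain-text `manifest.txt`
#' (config echo + file inventory) and `log.txt`.
#'
#' @param config A [run_config()].
#' @return The `contrast_run`, invisibly, with attribute `outdir`.
#' @export
run_dge_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cf <- config
  dir.create(cf$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file(file.path(cf$outdir, "log.txt"), open = "wt")
  on.exit(close(logfile))

  counts <- if (is.character(cf$counts)) read_counts(cf$counts) else assert_count_matrix(cf$counts)
  samples <- if (is.character(cf$metadata)) read_metadata(cf$metadata, cf$factor) else tibble::as_tibble(cf$metadata)
  log_line(logfile, "Loaded ", nrow(counts), " genes x ", ncol(counts), " samples.")

  covariates <- NULL
  if (cf$cleaning %in% c("prefilter", "both")) {
    pf <- prefilter(counts, samples, cf$factor)
    log_line(logfile, "Prefilter kept ", sum(pf$keep), "/", length(pf$keep), " genes.")
    write_table_csv(data.frame(gene = pf$kept_genes),
                    file.path(cf$outdir, "kept_genes.csv"))
    counts <- pf$counts
  }
  if (cf$cleaning %in% c("sva", "both")) {
    svres <- estimate_surrogate_variables(counts, samples, cf$factor,
                                          seed = cf$seed)
    log_line(logfile, "Estimated ", svres$n_sv, " surrogate variable(s).")
    samples <- svres$samples
    if (svres$n_sv > 0) {
      covariates <- paste0("SV", seq_len(svres$n_sv))
      write_sv_csv(svres, file.path(cf$outdir, "surrogate_variables.csv"))
    }
  }

  eng <- engine_config(mode = cf$mode, prior_sd = cf$prior_sd)
  thr <- deg_thresholds(alpha = cf$alpha, lfc_min = cf$lfc_min)
  run <- withCallingHandlers(
    run_all_contrasts(counts, samples, cf$factor, covariates = covariates,
                      config = eng, thresholds = thr),
    message = function(m) {
      writeLines(paste0(format(Sys.time(), "%H:%M:%S"), " INFO ",
                        trimws(conditionMessage(m))), logfile)
      invokeRestart("muffleMessage")
    })
  log_line(logfile, "Fitted ", length(run$tables), " contrasts (mode ",
           cf$mode, ").")

  cdir <- file.path(cf$outdir, "contrasts")
  for (nm in names(run$tables)) {
    d <- file.path(cdir, nm)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_deg_csv(run$degs[[nm]], file.path(d, "degs.csv"))
    if (cf$print_all) {
      write_result_table(run$tables[[nm]], file.path(d, "results.csv"))
      write_ranked_list(run$tables[[nm]], file.path(d, "ranked.rnk"))
    }
    if (cf$plots) {
      render("volcano", run$tables[[nm]], thr, file.path(d, "volcano.png"))
      render("ma", run$tables[[nm]], thr, file.path(d, "ma.png"))
    }
  }
  if (cf$plots) {
    render("pca", list(counts = counts, samples = samples, factor = cf$factor),
           outpath = file.path(cf$outdir, "pca.png"))
  }
  write_manifest(cf, cf$outdir)
  log_line(logfile, "Run complete: ", cf$outdir)
  invisible(structure(run, outdir = cf$outdir))
}

write_manifest <- function(cf, outdir) {
  files <- sort(list.files(outdir, recursive = TRUE))
  files <- setdiff(files, c("manifest.txt", "log.txt"))
  lines <- c(
    "# run manifest",
    paste0("factor=", cf$factor),
    paste0("mode=", cf$mode),
    paste0("prior_sd=", fmt_num(cf$prior_sd)),
    paste0("alpha=", fmt_num(cf$alpha)),
    paste0("lfc_min=", fmt_num(cf$lfc_min)),
    paste0("cleaning=", cf$cleaning),
    paste0("print_all=", cf$print_all),
    paste0("seed=", cf$seed),
    "# files",
    files)
  writeLines(lines, file.path(outdir, "manifest.txt"))
  invisible(lines)
}

read_manifest <- function(outdir) {
  lines <- readLines(file.path(outdir, "manifest.txt"))
  kv <- grep("^[a-z_]+=", lines, value = TRUE)
  vals <- sub("^[a-z_]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  as.list(vals)
}

#' Compare reciprocal contrasts of one or more run directories
#'
#' The diagnostic stage: reads the DEG lists of each run directory (multiple
#' directories enable before/after cleaning comparison; the first is the
#' baseline), builds a `mirror_report` per reciprocal pair per run, writes
#' per-pair concordant DEG CSVs, mirror-report CSVs, Venn and LFC-sum density
#' plots, the stacked-bar chart, the UpSet plot with its intersection-detail
#' CSV, and a one-line-per-pair verdict table with discordance percentage per
#' cleaning mode and the percentage change in concordant DEGs against the
#' baseline run.
#'
#' @param run_dirs Named character vector of run directories (names label the
#'   cleaning modes, e.g. `c(none = ..., prefilter = ...)`; unnamed
#'   directories are labelled `run1`, `run2`, ...).
#' @param outdir Output directory for the diagnostics (default
#'   `<first run>/diagnostics`).
#' @return A list: `reports` (per run: list of `mirror_report`s), `verdicts`
#'   (tibble), `intersections` (an `intersection_table`), invisibly.
#' @export
compare_runs <- function(run_dirs, outdir = NULL) {
  if (is.null(names(run_dirs)) || any(names(run_dirs) == "")) {
    names(run_dirs) <- paste0("run", seq_along(run_dirs))
  }
  outdir <- outdir %||% file.path(run_dirs[[1]], "diagnostics")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  mans <- lapply(run_dirs, read_manifest)
  thr <- unique(vapply(mans, function(m) paste(m$alpha, m$lfc_min), ""))
  if (length(thr) > 1) {
    abort("Run directories were produced with different DEG thresholds.")
  }

  load_run <- function(dir) {
    cdirs <- list.dirs(file.path(dir, "contrasts"), recursive = FALSE)
    degs <- lapply(cdirs, function(d) read_deg_csv(file.path(d, "degs.csv")))
    names(degs) <- basename(cdirs)
    tabs <- lapply(cdirs, function(d) {
      f <- file.path(d, "results.csv")
      if (file.exists(f)) read_result_table(f) else NULL
    })
    names(tabs) <- basename(cdirs)
    list(degs = degs, tables = tabs)
  }
  runs <- lapply(run_dirs, load_run)

  # warn when gene universes differ across runs (e.g. prefiltered vs not)
  universes <- lapply(runs, function(r) {
    u <- unique(unlist(lapply(r$tables, function(t) t$gene)))
    if (length(u)) u else unique(unlist(lapply(r$degs, function(d) d$gene)))
  })
  base_u <- universes[[1]]
  for (nm in names(universes)[-1]) {
    d1 <- length(setdiff(base_u, universes[[nm]]))
    d2 <- length(setdiff(universes[[nm]], base_u))
    if (d1 + d2 > 0) {
      warn(paste0("Gene universes differ: ", d1, " gene(s) absent from '", nm,
                  "', ", d2, " absent from '", names(universes)[1],
                  "'. Proceeding."))
    }
  }

  # reciprocal pairs from the contrast names of the first run
  contrasts <- names(runs[[1]]$degs)
  pairs <- list()
  for (nm in contrasts) {
    parts <- vapply(contrasts, function(o) {
      p <- tryCatch(strsplit_contrast(nm, o), error = function(e) NULL)
      !is.null(p)
    }, logical(1))
    rev_nm <- contrasts[parts][1]
    if (!is.na(rev_nm)) {
      key <- paste(sort(c(nm, rev_nm)), collapse = "|")
      # forward = alphabetically later test level
      fwd <- sort(c(nm, rev_nm), decreasing = TRUE)[1]
      pairs[[key]] <- c(fwd, setdiff(c(nm, rev_nm), fwd))
    }
  }

  reports <- list(); verdict_rows <- list()
  for (mode_nm in names(runs)) {
    r <- runs[[mode_nm]]
    reps <- list()
    for (key in names(pairs)) {
      fwd <- pairs[[key]][1]; rev <- pairs[[key]][2]
      if (!fwd %in% names(r$degs) || !rev %in% names(r$degs)) next
      rep <- classify_concordance(r$degs[[fwd]], r$degs[[rev]],
                                  forward = fwd, reverse = rev)
      reps[[key]] <- rep
      pdir <- file.path(outdir, mode_nm, gsub("[^A-Za-z0-9_.-]", "_", key))
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      conc <- r$degs[[fwd]] |> dplyr::filter(.data$gene %in% rep$concordant)
      write_deg_csv(conc, file.path(pdir, "concordant_degs.csv"))
      write_table_csv(dplyr::mutate(rep$genes,
                                    forward = fwd, reverse = rev),
                      file.path(pdir, "mirror_report.csv"))
      render("venn", rep, outpath = file.path(pdir, "venn.png"))
      if (!is.null(r$tables[[fwd]]) && length(rep$concordant) > 0) {
        sums <- lfc_mirror_sums(r$tables[[fwd]], r$tables[[rev]], rep$concordant)
        write_table_csv(sums$sums, file.path(pdir, "lfc_sums.csv"))
        render("density", sums, outpath = file.path(pdir, "lfc_density.png"))
      }
    }
    reports[[mode_nm]] <- reps
    render("stacked_bar", reps,
           outpath = file.path(outdir, paste0("stacked_bar_", mode_nm, ".png")))
    verdict_rows[[mode_nm]] <- purrr::map_dfr(reps, tidy, .id = "pair") |>
      dplyr::mutate(mode = mode_nm)
  }

  verdicts <- dplyr::bind_rows(verdict_rows)
  base_mode <- names(runs)[1]
  base_conc <- verdicts |> dplyr::filter(.data$mode == base_mode) |>
    dplyr::select("pair", before = "n_concordant")
  verdicts <- verdicts |>
    dplyr::left_join(base_conc, by = "pair") |>
    dplyr::mutate(pct_change_concordant = purrr::map2_dbl(
      .data$before, .data$n_concordant,
      function(b, a) as.numeric(pct_change_concordant(b, a)))) |>
    dplyr::select(-"before")
  write_table_csv(verdicts, file.path(outdir, "verdicts.csv"))

  # UpSet over the DEG sets of every contrast of the baseline run
  sets <- lapply(runs[[1]]$degs, function(d) d$gene)
  itab <- NULL
  if (length(sets) >= 2) {
    itab <- compute_intersections(sets)
    write_intersections_csv(itab, file.path(outdir, "intersections.csv"))
    render("upset", itab, outpath = file.path(outdir, "upset.png"))
  }
  inform(paste0("Diagnostics written to ", outdir))
  invisible(list(reports = reports, verdicts = verdicts, intersections = itab))
}

#' Simulate a dataset to files
#'
#' @param preset A [scenario_preset()] name, or `NULL` if `config` is given.
#' @param seed Seed.
#' @param outdir Output directory.
#' @param config Optional explicit [sim_config()] (overrides `preset`).
#' @param n_genes Number of genes for the preset.
#' @return The written paths (named), invisibly.
#' @export
simulate_to_dir <- function(preset = NULL, seed = 1, outdir, config = NULL,
                            n_genes = 2000) {
  config <- config %||% scenario_preset(preset, seed = seed, n_genes = n_genes)
  sim <- simulate_dataset(config)
  paths <- write_sim_dataset(sim, outdir)
  invisible(paths)
}
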