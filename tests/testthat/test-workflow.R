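wf_sim <- function(dir, seed = 401, n_genes = 80) {
  sim <- simulate_dataset(sim_config(n_genes = n_genes,
                                     group_sizes = c(A = 4, B = 4, C = 4),
                                     seed = seed))
  write_sim_dataset(sim, dir)
}

test_that("run_dge_workflow populates the documented directory layout", {
  d <- withr::local_tempdir()
  paths <- wf_sim(file.path(d, "data"))
  out <- file.path(d, "run1")
  cf <- run_config(counts = paths[["counts"]], metadata = paths[["metadata"]],
                   factor = "group", print_all = TRUE, plots = FALSE,
                   outdir = out, seed = 1)
  run <- suppressMessages(run_dge_workflow(cf))
  cdirs <- list.dirs(file.path(out, "contrasts"), recursive = FALSE)
  expect_identical(length(cdirs), 6L)              # k = 3 -> 6 contrasts
  for (cd in cdirs) {
    expect_true(file.exists(file.path(cd, "degs.csv")))
    expect_true(file.exists(file.path(cd, "results.csv")))
    expect_true(file.exists(file.path(cd, "ranked.rnk")))
    tab <- read_result_table(file.path(cd, "results.csv"))
    expect_identical(nrow(tab), 80L)               # full table = all genes
  }
  expect_true(file.exists(file.path(out, "manifest.txt")))
  expect_true(file.exists(file.path(out, "log.txt")))

  # print_all off -> no full tables on disk
  out2 <- file.path(d, "run2")
  cf2 <- run_config(counts = paths[["counts"]], metadata = paths[["metadata"]],
                    factor = "group", print_all = FALSE, plots = FALSE,
                    outdir = out2, seed = 1)
  suppressMessages(run_dge_workflow(cf2))
  expect_identical(
    length(list.files(out2, pattern = "^results\\.csv$", recursive = TRUE)), 0L)
})

test_that("identical configs reproduce identical run directories", {
  d <- withr::local_tempdir()
  paths <- wf_sim(file.path(d, "data"))
  outs <- file.path(d, c("a", "b"))
  for (o in outs) {
    suppressMessages(run_dge_workflow(run_config(
      counts = paths[["counts"]], metadata = paths[["metadata"]],
      factor = "group", print_all = TRUE, plots = FALSE, outdir = o, seed = 1)))
  }
  fa <- list.files(outs[1], recursive = TRUE)
  fb <- list.files(outs[2], recursive = TRUE)
  expect_identical(fa, fb)
  for (f in setdiff(fa, "log.txt")) {   # log carries timestamps
    expect_identical(readLines(file.path(outs[1], f)),
                     readLines(file.path(outs[2], f)),
                     info = f)
  }
})

test_that("compare_runs produces pair reports, verdicts and intersections", {
  d <- withr::local_tempdir()
  paths <- wf_sim(file.path(d, "data"), seed = 402)
  r1 <- file.path(d, "none"); r2 <- file.path(d, "prefilter")
  suppressMessages(run_dge_workflow(run_config(
    counts = paths[["counts"]], metadata = paths[["metadata"]],
    factor = "group", print_all = TRUE, plots = FALSE, outdir = r1, seed = 1)))
  suppressMessages(run_dge_workflow(run_config(
    counts = paths[["counts"]], metadata = paths[["metadata"]],
    factor = "group", cleaning = "prefilter", print_all = TRUE, plots = FALSE,
    outdir = r2, seed = 1)))
  dout <- file.path(d, "diag")
  res <- suppressWarnings(suppressMessages(
    compare_runs(c(none = r1, prefilter = r2), outdir = dout)))
  expect_identical(length(res$reports$none), 3L)   # k = 3 -> 3 pairs
  expect_identical(nrow(res$verdicts), 6L)         # 3 pairs x 2 modes
  expect_true(all(c("discordance_pct", "pct_change_concordant") %in%
                    names(res$verdicts)))
  # percent change populated for the non-baseline mode
  pf <- res$verdicts[res$verdicts$mode == "prefilter", ]
  expect_true(all(is.finite(pf$pct_change_concordant) |
                    is.na(pf$pct_change_concordant)))
  expect_true(file.exists(file.path(dout, "verdicts.csv")))
  expect_true(file.exists(file.path(dout, "intersections.csv")))
  expect_true(file.exists(file.path(dout, "upset.png")))
})

test_that("compare_runs rejects runs with mismatched thresholds", {
  d <- withr::local_tempdir()
  paths <- wf_sim(file.path(d, "data"), seed = 403, n_genes = 40)
  r1 <- file.path(d, "r1"); r2 <- file.path(d, "r2")
  suppressMessages(run_dge_workflow(run_config(
    counts = paths[["counts"]], metadata = paths[["metadata"]],
    factor = "group", plots = FALSE, outdir = r1, seed = 1)))
  suppressMessages(run_dge_workflow(run_config(
    counts = paths[["counts"]], metadata = paths[["metadata"]],
    factor = "group", alpha = 0.05, plots = FALSE, outdir = r2, seed = 1)))
  expect_error(compare_runs(c(r1, r2)), "different DEG thresholds")
})

test_that("command-line entry point runs, validates and simulates", {
  cli <- system.file("cli", "reciproqc", package = "reciproqc")
  expect_true(nzchar(cli))
  d <- withr::local_tempdir()
  run_cli <- function(...) {
    suppressWarnings(system2("Rscript", c(cli, ...), stdout = TRUE, stderr = TRUE))
  }
  status_of <- function(out) attr(out, "status") %||% 0L

  # simulate
  out <- run_cli("simulate", "--preset", "cellline", "--seed", "3",
                 "--n-genes", "60", "--outdir", file.path(d, "sim"))
  expect_identical(status_of(out), 0L)
  expect_true(file.exists(file.path(d, "sim", "counts.tsv")))

  # usage error before any computation
  out2 <- run_cli("run", "--counts", file.path(d, "sim", "counts.tsv"),
                  "--metadata", file.path(d, "sim", "metadata.csv"),
                  "--factor", "group", "--alpha", "1.5",
                  "--outdir", file.path(d, "bad"))
  expect_identical(status_of(out2), 2L)
  expect_false(dir.exists(file.path(d, "bad", "contrasts")))

  # a small real run (plots off to keep it quick)
  out3 <- run_cli("run", "--counts", file.path(d, "sim", "counts.tsv"),
                  "--metadata", file.path(d, "sim", "metadata.csv"),
                  "--factor", "group", "--no-plots",
                  "--outdir", file.path(d, "run"))
  expect_identical(status_of(out3), 0L)
  expect_identical(
    length(list.dirs(file.path(d, "run", "contrasts"), recursive = FALSE)),
    30L)                                          # k = 6 -> 30 contrasts
})
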