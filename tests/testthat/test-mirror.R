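test_that("concordance classification is plain set algebra", {
  fwd <- make_degset(c("g1", "g2", "g3"), "B-A", c(1L, 1L, -1L))
  rev <- make_degset(c("g2", "g3", "g4"), "A-B", c(-1L, -1L, 1L))
  rep <- suppressWarnings(classify_concordance(fwd, rev))
  expect_identical(rep$concordant, c("g2", "g3"))
  expect_identical(rep$discordant_fwd, "g1")
  expect_identical(rep$discordant_rev, "g4")
  # membership defines concordance; g3 has same sign both ways -> violation
  expect_identical(rep$sign_violations, "g3")
  expect_warning(classify_concordance(fwd, rev), "opposite directions")

  same <- suppressWarnings(classify_concordance(
    make_degset(c("x", "y"), "B-A"), make_degset(c("x", "y"), "A-B")))
  expect_identical(length(same$discordant_fwd) + length(same$discordant_rev), 0L)
  expect_equal(same$discordance_pct, 0)

  disj <- classify_concordance(make_degset("x", "B-A"), make_degset("y", "A-B"))
  expect_identical(disj$concordant, character(0))
  expect_equal(disj$discordance_pct, 100)
})

test_that("classification validates reciprocity and threshold identity", {
  expect_error(classify_concordance(make_degset("g", "B-A"),
                                    make_degset("g", "C-B")),
               "not reciprocal")
  expect_error(classify_concordance(make_degset("g", "B-A", alpha = 0.01),
                                    make_degset("g", "A-B", alpha = 0.05)),
               "different thresholds")
})

test_that("classification is symmetric in which contrast is called forward", {
  fwd <- make_degset(c("g1", "g2", "g3"), "B-A")
  rev <- make_degset(c("g2", "g5"), "A-B")
  a <- suppressWarnings(classify_concordance(fwd, rev))
  b <- suppressWarnings(classify_concordance(rev, fwd))
  expect_identical(a$concordant, b$concordant)
  expect_identical(a$discordant_fwd, b$discordant_rev)
  expect_identical(a$discordant_rev, b$discordant_fwd)
  expect_equal(a$discordance_pct, b$discordance_pct)
})

test_that("discordance percentage formula and degenerate conventions", {
  expect_equal(discordance_pct(list(concordant = 8, discordant_fwd = 2,
                                    discordant_rev = 0)), 20)
  expect_equal(discordance_pct(list(concordant = 5, discordant_fwd = 0,
                                    discordant_rev = 0)), 0)
  expect_equal(discordance_pct(list(concordant = 0, discordant_fwd = 0,
                                    discordant_rev = 0)), 0)
  expect_equal(discordance_pct(list(concordant = character(0),
                                    discordant_fwd = c("a", "b"),
                                    discordant_rev = "c")), 100)
})

test_that("percent change in concordant DEGs", {
  expect_equal(pct_change_concordant(100, 125), 25)
  expect_equal(pct_change_concordant(100, 100), 0)
  expect_equal(pct_change_concordant(100, 75), -25)
  out <- pct_change_concordant(0, 7)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})

test_that("LFC mirror sums: arithmetic, summary, missing-gene error", {
  f <- tibble::tibble(gene = c("a", "b"), log2FoldChange = c(2.5, 2.5))
  r <- tibble::tibble(gene = c("a", "b"), log2FoldChange = c(-2.5, -2.1))
  out <- lfc_mirror_sums(f, r, c("a", "b"))
  expect_equal(out$sums$lfc_sum, c(0, 0.4))
  expect_equal(out$summary$max_abs, 0.4)
  expect_error(lfc_mirror_sums(f, r, c("a", "zz")), "zz")
})

test_that("mirror sums vanish end-to-end under the unshrunk engine", {
  sim <- quick_sim(seed = 51, n_genes = 150)
  run <- suppressMessages(run_all_contrasts(sim$counts, sim$samples, "group"))
  reps <- mirror_reports(run)
  for (key in names(reps)) {
    rep <- reps[[key]]
    if (length(rep$concordant) == 0) next
    sums <- lfc_mirror_sums(run$tables[[rep$forward]],
                            run$tables[[rep$reverse]], rep$concordant)
    expect_lt(sums$summary$max_abs, 1e-6)
  }
})

test_that("expression-split test detects lower-expressed discordant genes", {
  set.seed(61)
  rep <- list(genes = dplyr::bind_rows(
    tibble::tibble(gene = sprintf("c%02d", 1:40), category = "concordant"),
    tibble::tibble(gene = sprintf("f%02d", 1:30), category = "discordant_fwd"),
    tibble::tibble(gene = sprintf("r%02d", 1:30), category = "discordant_rev")))
  bm <- c(rlnorm(40, log(500), 0.5), rlnorm(30, log(50), 0.5),
          rlnorm(30, log(50), 0.5))
  names(bm) <- rep$genes$gene
  out <- expression_split_test(rep, bm)
  expect_lt(out$global_p, 0.05)
  pw <- out$pairwise
  expect_lt(pw$p[pw$cat1 == "concordant" & pw$cat2 == "discordant_fwd"], 0.05)
  expect_lt(pw$p[pw$cat1 == "concordant" & pw$cat2 == "discordant_rev"], 0.05)
})

test_that("expression-split test skips empty categories gracefully", {
  rep <- list(genes = dplyr::bind_rows(
    tibble::tibble(gene = paste0("c", 1:10), category = "concordant"),
    tibble::tibble(gene = paste0("f", 1:10), category = "discordant_fwd")))
  bm <- setNames(rlnorm(20, log(100), 1), rep$genes$gene)
  out <- expression_split_test(rep, bm)
  expect_identical(nrow(out$pairwise), 1L)  # only the one nonempty pair

  rep1 <- list(genes = tibble::tibble(gene = paste0("c", 1:10),
                                      category = "concordant"))
  out1 <- expression_split_test(rep1, bm[1:10])
  expect_true(is.na(out1$global_p))
  expect_true(attr(out1$global_p, "undefined"))
})

test_that("exclusive intersections: worked example and partition invariant", {
  itab <- compute_intersections(list(X = c("a", "b", "c"), Y = c("b", "c", "d")))
  get <- function(nm) itab$genes[[match(nm, itab$intersection)]]
  expect_identical(get("X"), "a")
  expect_identical(get("Y"), "d")
  expect_identical(get("X&Y"), c("b", "c"))
  expect_identical(sum(itab$size), 4L)
  expect_error(compute_intersections(list(X = "a")), "at least 2")
  expect_error(compute_intersections(setNames(list("a", "b"), c("X", "X"))),
               "uniquely named")
})

test_that("exclusive intersections match brute-force enumeration on random sets", {
  set.seed(71)
  universe <- sprintf("g%03d", 1:120)
  for (trial in 1:100) {
    k <- sample(2:4, 1)
    sets <- setNames(lapply(seq_len(k), function(i) {
      sample(universe, sample(10:50, 1))
    }), paste0("S", seq_len(k)))
    itab <- compute_intersections(sets)
    oracle <- brute_force_intersections(sets)
    got <- setNames(itab$genes, itab$intersection)
    # same patterns with same members
    norm_key <- function(nm) paste(sort(strsplit(nm, "&", fixed = TRUE)[[1]]),
                                   collapse = "&")
    names(got) <- vapply(names(got), norm_key, "")
    names(oracle) <- vapply(names(oracle), norm_key, "")
    expect_setequal(names(got), names(oracle))
    for (nm in names(oracle)) expect_identical(got[[nm]], oracle[[nm]])
    # partition of the union
    expect_identical(sum(itab$size), length(unique(unlist(sets))))
    expect_identical(anyDuplicated(unlist(itab$genes)), 0L)
  }
})

test_that("intersection CSV details one gene per row with memberships", {
  itab <- compute_intersections(list(X = c("a", "b"), Y = c("b", "c")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_intersections_csv(itab, f)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), 3L)
  expect_setequal(back$gene, c("a", "b", "c"))
  expect_true(all(c("X", "Y") %in% names(back)))
})
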