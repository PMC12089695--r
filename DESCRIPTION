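Package: reciproqc
Title: Reciprocal-Contrast Concordance QC for Multi-Group Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-group bulk RNA-seq differential expression with
    reference-swapping extraction of every ordered contrast, and diagnosis of
    "mirror-check" failures: discordance between reciprocal contrasts that
    log-fold-change shrinkage introduces on sparse or highly variable data.
    Includes a negative-binomial Wald engine with optional ridge (zero-centered
    normal prior) shrinkage, concordance classification and discordance
    statistics for every reciprocal pair, low-count prefiltering and a
    simplified surrogate-variable estimator for data cleaning, a seeded
    negative-binomial simulator with ground truth, and diagnostic graphics
    (volcano, MA, Venn, stacked-bar, LFC-sum density, UpSet, heatmap, PCA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
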