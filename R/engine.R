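#' Engine configuration
#'
#' Settings for the negative-binomial Wald engine and its LFC shrinkage.
#'
#' @param mode Shrinkage mode: `"none"` (plain Wald estimates), `"ridge"`
#'   (maximum a-posteriori refit under independent zero-centered normal priors
#'   on all non-intercept coefficients), or `"backend:<name>"` to delegate to a
#'   backend registered with [register_shrinkage_backend()].
#' @param prior_sd Prior standard deviation for ridge shrinkage, in log2
#'   units. The default `"auto"` estimates it from the data by moment
#'   matching: the prior variance is the mean over tested genes and
#'   coefficients of `max(b^2 - se^2, 0)` (the excess of the squared MLE over
#'   its squared standard error), floored at 0.05^2. A fixed positive number
#'   pins it instead.
#' @param dispersion_floor Lower bound for per-gene NB dispersion.
#' @param max_iterations Maximum IRLS iterations per gene.
#' @param convergence_tol Relative deviance-change tolerance for IRLS.
#' @return An `engine_config` list.
#' @export
engine_config <- function(mode = "none", prior_sd = "auto",
                          dispersion_floor = 1e-8,
                          max_iterations = 100L, convergence_tol = 1e-10) {
  if (!(mode %in% c("none", "ridge") || startsWith(mode, "backend:"))) {
    abort("`mode` must be 'none', 'ridge', or 'backend:<name>'.")
  }
  if (!identical(prior_sd, "auto")) {
    stopifnot(is.numeric(prior_sd), length(prior_sd) == 1, prior_sd > 0)
  }
  stopifnot(dispersion_floor > 0, max_iterations >= 1, convergence_tol > 0)
  structure(list(mode = mode, prior_sd = prior_sd,
                 dispersion_floor = dispersion_floor,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "engine_config")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization scalars: for each sample, the median over genes
#' (restricted to genes with an all-positive row, hence a positive geometric
#' mean) of the ratio of the sample's count to the gene's geometric mean.
#' If no gene has all-positive counts, the median is taken per sample over the
#' genes with a positive count in that sample, with a warning.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("g1","g2"), c("a","b")))
#' estimate_size_factors(m) # c(1/sqrt(2), sqrt(2))
estimate_size_factors <- function(counts) {
  counts <- assert_count_matrix(counts)
  if (all(counts == 0)) abort("All counts are zero; size factors undefined.")
  log_geo <- rowMeans(log(counts))            # -Inf for any row with a zero
  usable <- is.finite(log_geo)
  if (any(usable)) {
    lr <- log(counts[usable, , drop = FALSE]) - log_geo[usable]
    sf <- exp(apply(lr, 2, median))
  } else {
    warn("No gene has positive counts in every sample; falling back to per-sample positive-subset medians.")
    log_geo_pos <- apply(counts, 1, function(r) mean(log(r[r > 0])))
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      pos <- counts[, j] > 0 & is.finite(log_geo_pos)
      exp(median(log(counts[pos, j]) - log_geo_pos[pos]))
    }, numeric(1))
    names(sf) <- colnames(counts)
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    abort("Size factor estimation failed (non-positive factor).")
  }
  sf
}

# NB deviance (-2 * loglik up to a beta-free constant), safe at y = 0
nb_deviance <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-10)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu))
  2 * sum(t1 - t2)
}

# single-gene IRLS for the NB log-link GLM; `penalty` is the diagonal of the
# quadratic penalty matrix on natural-log coefficients (0 = ML fit)
irls_nb <- function(y, X, offset, alpha, penalty = NULL, beta0 = NULL,
                    tol = 1e-10, maxit = 100L) {
  p <- ncol(X)
  if (is.null(penalty)) penalty <- rep(0, p)
  if (is.null(beta0)) {
    beta0 <- tryCatch(qr.solve(X, log(pmax(y, 0.5)) - offset),
                      error = function(e) c(log(mean(pmax(y, 0.5))), rep(0, p - 1)))
  }
  beta <- beta0
  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(pmin(eta, 700)), 1e-10)
  obj <- nb_deviance(y, mu, alpha) + sum(penalty * beta^2)
  converged <- FALSE
  A <- NULL
  for (it in seq_len(maxit)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X
    diag(A) <- diag(A) + penalty
    beta_new <- tryCatch(drop(solve(A, XtW %*% z)), error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) break
    # a negligible full Newton step means we are at the optimum already
    if (max(abs(beta_new - beta)) < 1e-9) { converged <- TRUE; break }
    # step-halving to guarantee descent of the (penalized) deviance
    step <- beta_new - beta
    ok <- FALSE
    for (h in 0:10) {
      cand <- beta + step * (0.5^h)
      eta_c <- drop(X %*% cand) + offset
      mu_c <- pmax(exp(pmin(eta_c, 700)), 1e-10)
      obj_c <- nb_deviance(y, mu_c, alpha) + sum(penalty * cand^2)
      if (is.finite(obj_c) && obj_c <= obj + 1e-10 * (abs(obj) + 1)) { ok <- TRUE; break }
    }
    if (!ok) break
    dev_delta <- abs(obj - obj_c) / (abs(obj_c) + 0.1)
    beta_delta <- max(abs(cand - beta))
    beta <- cand; eta <- eta_c; mu <- mu_c; obj <- obj_c
    if (dev_delta < tol && beta_delta < 1e-8) { converged <- TRUE; break }
  }
  # a coefficient running away (e.g. a group with all-zero counts has its
  # true MLE at -infinity) is flagged, not reported as a converged test
  if (p > 1 && max(abs(beta[-1])) > 15) converged <- FALSE
  # observed (expected-information) curvature at the solution
  w <- mu / (1 + alpha * mu)
  XtWX <- t(X * w) %*% X
  Ainfo <- XtWX
  diag(Ainfo) <- diag(Ainfo) + penalty
  cov <- tryCatch(solve(Ainfo), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, cov = cov, mu = mu, converged = converged, deviance = obj)
}

# gene-wise ML dispersion given fitted means, on the log scale; also returns
# the curvature-based sampling variance of log(alpha-hat), used as the
# precision weight in the empirical-Bayes moderation toward the trend
ml_dispersion <- function(y, mu, lower = 1e-8, upper = 100) {
  nll <- function(la) -sum(dnbinom(y, size = 1 / exp(la), mu = mu, log = TRUE))
  opt <- optimize(nll, c(log(lower), log(upper)), tol = 1e-6)
  la <- opt$minimum
  h <- 0.05
  var_la <- Inf
  if (la > log(lower) + h && la < log(upper) - h) {
    curv <- (nll(la + h) - 2 * opt$objective + nll(la - h)) / h^2
    if (is.finite(curv) && curv > 0) var_la <- 1 / curv
  }
  list(alpha = exp(la), var_log = var_la)
}

# parametric mean-dispersion trend alpha(mu) = a0 + a1/mu via Gamma GLM,
# iterated with exclusion of genes far off the trend (ratio outside
# [1/10, 10]) so a handful of outliers cannot swing it; median fallback when
# the GLM cannot be fit
fit_dispersion_trend <- function(disp, base_mean, floor = 1e-8) {
  use <- is.finite(disp) & disp > 1e-7 & base_mean > 0
  if (sum(use) >= 10) {
    keep <- use
    a <- NULL
    for (it in 1:3) {
      fit <- tryCatch(
        glm(disp[keep] ~ I(1 / base_mean[keep]),
            family = Gamma(link = "identity"),
            start = c(median(disp[keep]), 1)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || !all(is.finite(coef(fit)))) break
      a <- coef(fit)
      pred <- pmax(a[1] + a[2] / pmax(base_mean, 1e-8), floor)
      ratio <- disp / pred
      keep_new <- use & ratio > 0.1 & ratio < 10
      if (sum(keep_new) < 10 || identical(keep_new, keep)) break
      keep <- keep_new
    }
    if (!is.null(a)) {
      return(function(mu) pmax(a[1] + a[2] / pmax(mu, 1e-8), floor))
    }
  }
  m <- if (any(use)) median(disp[use]) else floor
  function(mu) rep(max(m, floor), length(mu))
}

#' Fit the per-gene negative-binomial model for one reference level
#'
#' Fits, per gene, a negative-binomial log-link GLM of counts on the design
#' factor (coefficients relative to `reference`) plus any covariates, with
#' median-of-ratios size factors as offsets. Dispersion is estimated gene-wise
#' by maximum likelihood (floored), then moderated 50/50 on the log scale
#' toward a parametric trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} fitted across
#' genes. Wald statistics for any contrast against the reference are available
#' through [contrast_results()].
#'
#' @param counts Gene-by-sample count matrix.
#' @param samples Sample metadata with `sample_id`, the design factor, and any
#'   covariate columns.
#' @param factor Name of the design factor column in `samples`.
#' @param reference Reference level of the factor.
#' @param covariates Character vector of covariate column names (numeric or
#'   categorical) to adjust for, e.g. surrogate variables.
#' @param config An [engine_config()].
#' @param dispersions Optional precomputed final dispersions (named by gene);
#'   when supplied (e.g. to share one estimate across reference-swapped fits),
#'   estimation is skipped.
#' @return A `dge_fit` object.
#' @export
fit_dge <- function(counts, samples, factor, reference, covariates = NULL,
                    config = engine_config(), dispersions = NULL) {
  counts <- assert_count_matrix(counts)
  samples <- align_samples(counts, samples)
  if (!factor %in% names(samples)) {
    abort(paste0("Factor column '", factor, "' not found in samples."))
  }
  fac <- as.factor(samples[[factor]])
  lv <- levels(fac)[levels(fac) %in% unique(as.character(fac))]
  fac <- base::factor(as.character(fac), levels = lv)
  if (!reference %in% lv) {
    abort(paste0("Reference level '", reference, "' is not a level of '",
                 factor, "' (levels: ", paste(lv, collapse = ", "), ")."))
  }
  n_per <- table(fac)
  if (any(n_per < 2)) {
    abort(paste0("Every level needs >= 2 samples for model fitting; offending: ",
                 paste(names(n_per)[n_per < 2], collapse = ", "), "."))
  }
  fac <- stats::relevel(fac, ref = reference)
  dd <- data.frame(..group.. = fac)
  for (cv in covariates %||% character(0)) {
    if (!cv %in% names(samples)) abort(paste0("Covariate '", cv, "' not found."))
    dd[[cv]] <- if (is.character(samples[[cv]])) base::factor(samples[[cv]]) else samples[[cv]]
  }
  form <- if (length(covariates)) {
    stats::as.formula(paste("~ ..group.. +", paste(covariates, collapse = " + ")))
  } else ~ ..group..
  X <- model.matrix(form, data = dd)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank-deficient; collinear column(s): ",
                 paste(bad, collapse = ", "), "."))
  }
  test_levels <- setdiff(lv, reference)
  coef_of <- setNames(match(paste0("..group..", test_levels), colnames(X)),
                      test_levels)

  sf <- estimate_size_factors(counts)
  offset <- log(sf)
  norm_counts <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm_counts)
  G <- nrow(counts); p <- ncol(X)
  tol <- config$convergence_tol; maxit <- config$max_iterations
  floor <- config$dispersion_floor

  nonzero <- rowSums(counts) > 0
  disp_genewise <- rep(NA_real_, G)
  disp_varlog <- rep(Inf, G)

  if (is.null(dispersions)) {
    # method-of-moments start from group means of normalized counts
    gm <- t(apply(norm_counts, 1, function(z) tapply(z, fac, mean)))
    mu0 <- gm[, as.character(fac), drop = FALSE] * rep(sf, each = G)
    for (g in which(nonzero)) {
      y <- counts[g, ]; m0 <- pmax(mu0[g, ], 1e-8)
      a_mom <- max((sum((y - m0)^2 - m0)) / sum(m0^2), floor)
      a_mom <- min(a_mom, 100)
      f1 <- irls_nb(y, X, offset, a_mom, tol = tol, maxit = maxit)
      a1 <- ml_dispersion(y, f1$mu, lower = floor)$alpha
      f2 <- irls_nb(y, X, offset, a1, beta0 = f1$beta, tol = tol, maxit = maxit)
      d2 <- ml_dispersion(y, f2$mu, lower = floor)
      disp_genewise[g] <- d2$alpha
      disp_varlog[g] <- d2$var_log
    }
    trend_fun <- fit_dispersion_trend(disp_genewise, base_mean, floor)
    disp_trend <- trend_fun(base_mean)
    # empirical-Bayes moderation: weight the gene-wise ML estimate by its
    # precision against the spread of true log-dispersions around the trend
    resid_log <- log(pmax(disp_genewise, floor)) - log(pmax(disp_trend, floor))
    informative <- nonzero & is.finite(disp_varlog)
    tau2_disp <- 0.25^2
    if (sum(informative) >= 10) {
      tau2_disp <- max(mean(resid_log[informative]^2 - disp_varlog[informative]),
                       0.25^2)
    }
    w <- ifelse(is.finite(disp_varlog),
                tau2_disp / (tau2_disp + disp_varlog), 0)
    disp_final <- pmax(exp(w * log(pmax(disp_genewise, floor)) +
                             (1 - w) * log(pmax(disp_trend, floor))), floor)
    disp_final[!nonzero] <- NA_real_
  } else {
    disp_final <- unname(dispersions[rownames(counts)])
    disp_trend <- rep(NA_real_, G)
  }

  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(counts), colnames(X)))
  covs <- array(NA_real_, c(p, p, G))
  conv <- rep(FALSE, G)
  for (g in which(nonzero)) {
    f <- irls_nb(counts[g, ], X, offset, disp_final[g], tol = tol, maxit = maxit)
    beta[g, ] <- f$beta
    covs[, , g] <- f$cov
    conv[g] <- f$converged
  }
  n_nc <- sum(nonzero & !conv)
  if (n_nc > 0) inform(paste0(n_nc, " gene(s) did not converge; their tests are reported as missing."))

  structure(list(
    counts = counts, samples = samples, factor = factor,
    reference = reference, levels = lv, test_levels = test_levels,
    covariates = covariates %||% character(0),
    design = X, coef_of = coef_of, size_factors = sf,
    base_mean = setNames(base_mean, rownames(counts)),
    dispersions = setNames(disp_final, rownames(counts)),
    dispersions_genewise = setNames(disp_genewise, rownames(counts)),
    beta = beta, cov = covs, converged = setNames(conv, rownames(counts)),
    nonzero = setNames(nonzero, rownames(counts)),
    config = config, shrunk = NULL), class = "dge_fit")
}

#' @export
print.dge_fit <- function(x, ...) {
  cat("<dge_fit> ", nrow(x$counts), " genes x ", ncol(x$counts), " samples; factor '",
      x$factor, "' (reference '", x$reference, "'), ",
      length(x$test_levels), " test level(s)\n", sep = "")
  invisible(x)
}

#' Moment-matched ridge prior scale
#'
#' Estimates the standard deviation (log2 units) of the zero-centered normal
#' prior from the data: the prior variance is the mean, over every unordered
#' pairwise contrast of the design factor and every tested gene, of
#' `max(b^2 - se^2, 0)` — the excess of the squared MLE log fold change over
#' its squared standard error, i.e. a moment estimate of the spread of true
#' effects. The estimate uses all pairwise contrasts (not only those against
#' the fit's reference), so it is a property of the dataset, invariant to the
#' reference parameterization, and shared across reference-swapped fits.
#' Low-count genes whose noisy contrasts carry no detectable excess signal
#' dilute the mean — the channel through which a sparse gene fraction
#' tightens everyone's shrinkage.
#'
#' @param fit A `dge_fit`.
#' @param floor_sd Lower bound for the returned sd (default 0.05 log2 units).
#' @return A single positive number.
#' @export
estimate_prior_sd <- function(fit, floor_sd = 0.05) {
  ln2 <- log(2)
  p <- ncol(fit$design)
  idx <- c(0, unname(fit$coef_of))          # 0 = the reference itself
  vals <- c()
  for (a in seq_along(idx)) {
    for (b_ in seq_len(a - 1L)) {
      cvec <- rep(0, p)
      if (idx[a] > 0) cvec[idx[a]] <- 1
      if (idx[b_] > 0) cvec[idx[b_]] <- -1
      b <- (fit$beta %*% cvec) / ln2
      s2 <- apply(fit$cov, 3, function(S) drop(cvec %*% S %*% cvec)) / ln2^2
      ok <- fit$converged & is.finite(b) & is.finite(s2)
      vals <- c(vals, pmax(b[ok]^2 - s2[ok], 0))
    }
  }
  if (length(vals) == 0) return(1)
  sqrt(max(mean(vals), floor_sd^2))
}

# ridge MAP refit of all coefficients for every gene; prior is zero-centered
# normal with sd `prior_sd` log2 units on all non-intercept coefficients
shrink_fit <- function(fit, prior_sd = fit$config$prior_sd) {
  if (identical(prior_sd, "auto")) prior_sd <- estimate_prior_sd(fit)
  X <- fit$design; p <- ncol(X)
  sd_nat <- prior_sd * log(2)
  penalty <- c(0, rep(1 / sd_nat^2, p - 1))
  G <- nrow(fit$counts)
  beta_s <- matrix(NA_real_, G, p, dimnames = dimnames(fit$beta))
  cov_s <- array(NA_real_, c(p, p, G))
  offset <- log(fit$size_factors)
  for (g in which(fit$nonzero)) {
    f <- irls_nb(fit$counts[g, ], X, offset, fit$dispersions[g],
                 penalty = penalty, beta0 = fit$beta[g, ],
                 tol = fit$config$convergence_tol,
                 maxit = fit$config$max_iterations)
    beta_s[g, ] <- f$beta
    cov_s[, , g] <- f$cov
  }
  fit$shrunk <- list(prior_sd = prior_sd, beta = beta_s, cov = cov_s)
  fit
}

#' Extract the result table for one contrast from a fitted engine
#'
#' Wald test of the `test` level against the fit's reference: `log2FoldChange`
#' is the test-over-reference coefficient in log2 units, `lfcSE` its standard
#' error, `pvalue` the two-sided normal p of the Wald z, and `padj` the
#' Benjamini-Hochberg adjustment over all tested genes. With `mode = "ridge"`
#' the LFC and SE come from the ridge MAP refit while `pvalue`/`padj` are
#' carried over from the unshrunk test (shrinkage alters ranking, not the
#' test).
#'
#' @param fit A `dge_fit`.
#' @param test A non-reference level of the design factor.
#' @param mode `"none"` or `"ridge"`; defaults to the fit's configured mode.
#' @return A tibble with columns `gene, baseMean, log2FoldChange, lfcSE,
#'   pvalue, padj, contrast, mode`, one row per gene.
#' @export
contrast_results <- function(fit, test, mode = NULL) {
  stopifnot(inherits(fit, "dge_fit"))
  mode <- mode %||% fit$config$mode
  if (!test %in% fit$test_levels) {
    abort(paste0("'", test, "' is not a test level of this fit (reference '",
                 fit$reference, "')."))
  }
  j <- fit$coef_of[[test]]
  ln2 <- log(2)
  b <- fit$beta[, j]
  se <- sqrt(fit$cov[j, j, ])
  ok <- fit$nonzero & fit$converged & is.finite(b) & is.finite(se) & se > 0
  z <- ifelse(ok, b / se, NA_real_)
  pval <- 2 * pnorm(-abs(z))
  padj <- bh_adjust(pval)
  if (mode == "ridge") {
    if (is.null(fit$shrunk)) fit <- shrink_fit(fit)
    lfc <- fit$shrunk$beta[, j] / ln2
    lfc_se <- sqrt(fit$shrunk$cov[j, j, ]) / ln2
  } else {
    lfc <- b / ln2
    lfc_se <- se / ln2
  }
  lfc[!fit$nonzero] <- 0
  tibble::tibble(
    gene = rownames(fit$counts),
    baseMean = unname(fit$base_mean),
    log2FoldChange = unname(ifelse(fit$nonzero, lfc, 0)),
    lfcSE = unname(ifelse(ok, lfc_se, NA_real_)),
    pvalue = unname(pval),
    padj = unname(padj),
    contrast = paste0(test, "-", fit$reference),
    mode = mode)
}

#' Fit one reference level and extract all its contrasts
#'
#' Convenience wrapper: one engine fit with `reference` as the reference
#' level, then one result table per non-reference level (shrinkage applied
#' according to `config$mode`).
#'
#' @inheritParams fit_dge
#' @return Named list of contrast result tables, names `"<Test>-<Reference>"`.
#' @export
fit_and_test <- function(counts, samples, factor, reference, covariates = NULL,
                         config = engine_config(), dispersions = NULL) {
  fit <- fit_dge(counts, samples, factor, reference, covariates, config,
                 dispersions)
  if (config$mode == "ridge") fit <- shrink_fit(fit)
  tabs <- lapply(fit$test_levels, function(tl) contrast_results(fit, tl))
  names(tabs) <- paste0(fit$test_levels, "-", reference)
  attr(tabs, "fit") <- fit
  tabs
}

#' Apply LFC shrinkage to an already-extracted result table
#'
#' Replaces `log2FoldChange`/`lfcSE` with ridge maximum a-posteriori estimates
#' refit from the model state, leaving `pvalue`/`padj` untouched. Backend
#' modes delegate to a registered backend.
#'
#' @param table A contrast result table from [contrast_results()].
#' @param fit The `dge_fit` the table came from.
#' @param config An [engine_config()] with `mode != "none"`.
#' @return The table with shrunk LFC estimates and the `mode` column updated.
#' @export
shrink_lfc <- function(table, fit, config = engine_config(mode = "ridge")) {
  if (config$mode == "none") abort("`shrink_lfc()` requires mode != 'none'.")
  if (startsWith(config$mode, "backend:")) {
    be <- backend_name(config$mode)
    fun <- get_backend(be)
    test <- sub(paste0("-", fit$reference, "$"), "", table$contrast[1])
    out <- fun(fit$counts, fit$samples, fit$factor, fit$reference, be)
    return(validate_backend_table(out[[paste0(test, "-", fit$reference)]] %||% out[[1]]))
  }
  if (is.null(fit$shrunk) || !identical(fit$shrunk$prior_sd, config$prior_sd)) {
    fit <- shrink_fit(fit, config$prior_sd)
  }
  test <- sub(paste0("-", fit$reference, "$"), "", table$contrast[1])
  shr <- contrast_results(fit, test, mode = "ridge")
  table$log2FoldChange <- shr$log2FoldChange
  table$lfcSE <- shr$lfcSE
  table$mode <- "ridge"
  table
}

#' Benjamini-Hochberg adjustment over the non-missing entries
#'
#' Step-up FDR adjustment applied to the non-missing p-values only; missing
#' entries stay missing and do not count toward the number of tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @return Adjusted p-values, same length and `NA` pattern.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

# --- shrinkage backend registry ----------------------------------------------

.backends <- new.env(parent = emptyenv())

backend_name <- function(mode) sub("^backend:", "", mode)

#' Register or list external shrinkage backends
#'
#' A backend is a function `(counts, samples, factor, reference, mode)`
#' returning a named list of contrast result tables (schema as
#' [contrast_results()]); the toolkit validates the schema only. This is the
#' hook for plugging in apeglm- or ashr-style estimators without
#' re-implementing them here.
#'
#' @param name Backend name (used as `mode = "backend:<name>"`).
#' @param fun The backend function.
#' @return `register_shrinkage_backend()` returns `name` invisibly;
#'   `list_shrinkage_backends()` returns a character vector.
#' @export
register_shrinkage_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = .backends)
  invisible(name)
}

#' @rdname register_shrinkage_backend
#' @export
list_shrinkage_backends <- function() sort(ls(.backends))

get_backend <- function(name) {
  if (!exists(name, envir = .backends, inherits = FALSE)) {
    abort(paste0("No shrinkage backend '", name, "' registered. Registered: ",
                 if (length(list_shrinkage_backends())) paste(list_shrinkage_backends(), collapse = ", ") else "(none)", "."))
  }
  get(name, envir = .backends, inherits = FALSE)
}

validate_backend_table <- function(tab) {
  need <- c("gene", "baseMean", "log2FoldChange", "lfcSE", "pvalue", "padj")
  if (!all(need %in% names(tab))) {
    abort(paste0("Backend table is missing column(s): ",
                 paste(setdiff(need, names(tab)), collapse = ", "), "."))
  }
  tibble::as_tibble(tab)
}
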