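---
title: "Reciprocal-contrast concordance QC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal-contrast concordance QC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reciproqc)
```

## The problem

In multi-group differential expression analysis, log fold changes (LFCs) are
defined relative to a reference level of the design factor. Unshrunk
negative-binomial Wald estimates are exactly antisymmetric under reference
exchange: the contrast A-vs-B is the negative of B-vs-A, with the same
p-value. Shrinkage estimators that moderate LFCs toward zero break this
symmetry for designs with three or more groups, because the set of penalized
coefficients changes with the reference. A gene can then pass the DEG
thresholds with one reference and fail them with the other — a *mirror-check
failure*. On sparse or highly variable data the effect is large enough to
change which genes an analyst takes forward.

`reciproqc` makes this failure measurable and actionable: it runs the
engine with every group as the reference in turn, classifies each reciprocal
pair's DEGs as concordant (present in both directions) or discordant
(present under only one reference), quantifies the discordance, and evaluates
two cleaning strategies — low-count prefiltering and surrogate-variable
adjustment — by how much they restore concordance.

## The engine

Counts $K_{gj}$ for gene $g$, sample $j$ are modeled as negative binomial
with mean $\mu_{gj} = s_j q_{gj}$ and variance $\mu + \alpha_g \mu^2$, with a
log-link GLM $\log q_{gj} = x_j^\top \beta_g$ on the design factor
(coefficients relative to the chosen reference) plus optional covariates.

* **Size factors** $s_j$ are median-of-ratios: the median over genes with an
  all-positive row of $K_{gj} / (\prod_{j'} K_{gj'})^{1/n}$. They are
  invariant to globally rescaling the matrix; if no gene is positive
  everywhere, a per-sample positive-subset median is used with a warning.
* **Fitting** is per-gene IRLS (Fisher scoring with working weights
  $\mu/(1+\alpha\mu)$), deviance step-halving, and a dual convergence rule
  (relative deviance change $<10^{-10}$ *and* max coefficient step
  $<10^{-8}$, or a negligible full Newton step). Genes whose MLE runs away
  (a group with all-zero counts has its optimum at $-\infty$; flagged at
  $|\beta|>15$ on the natural-log scale) or fail to converge are reported
  with missing p-values, never silently. The tight tolerance is what makes
  reciprocal unshrunk LFCs agree to $\sim 10^{-9}$ — the analytic baseline
  the mirror diagnostics measure against.
* **Dispersion** is estimated gene-wise by profile maximum likelihood
  (floored at $10^{-8}$), then moderated toward a parametric trend
  $\alpha(\mu) = a_0 + a_1/\mu$ fitted across genes by a Gamma GLM that
  iteratively excludes $>10\times$ outliers. Moderation is empirical-Bayes:
  on the log scale, the gene-wise estimate is weighted by its precision
  (the curvature of the profile likelihood at the optimum) against the
  moment-estimated spread of true log-dispersions around the trend, floored
  at $0.25^2$. Low-information genes are pulled almost fully to the trend;
  well-measured genes keep their own estimate. An earlier fixed 50/50 blend
  was abandoned: it leaves low-count genes' standard errors insensitive to
  the rest of the dataset, severing the cross-gene coupling through which a
  sparse gene fraction degrades — and prefiltering restores — shrinkage
  behavior.
* **Tests** are two-sided Wald ($z = \beta/\mathrm{SE}$, normal reference)
  with Benjamini–Hochberg adjustment over the non-missing p-values of each
  contrast table. There is no independent filtering and no outlier
  replacement: every converged gene gets a p-value, and missing adjusted
  p-values can only enter through ingested external tables. DEG calls use
  strict inequalities (adjusted p $< \alpha$, $|\mathrm{LFC}| >$ cutoff;
  defaults 0.01 and 2), and a missing adjusted p excludes the gene.

One engine fit is performed per reference level ($k$ fits for $k$ groups);
dispersions are estimated once, on the first fit, and shared across the
reference-swapped refits, since the dispersion model does not depend on the
parameterization.

## Ridge shrinkage and why it is reference-dependent

`mode = "ridge"` refits each gene at the fitted dispersion as a maximum
a-posteriori estimate under independent zero-centered normal priors (sd
`prior_sd`, log2 units) on all non-intercept coefficients; p-values are
carried over from the unshrunk test (shrinkage reranks genes, it does not
retest them). For $k = 2$ the reparameterization $(\beta_0, \beta_1) \mapsto
(\beta_0+\beta_1, -\beta_1)$ preserves both likelihood and penalty, so
shrunk LFCs mirror exactly. For $k \ge 3$ the penalized set changes with the
reference — under reference A the penalty falls on $\{\beta_B, \beta_C\}$,
under B on $\{-\beta_B, \beta_C - \beta_B\}$ — and the MAP contrast
estimates differ. The asymmetry is largest for weakly identified
(low-count, high-dispersion) genes, which is exactly where mirror-check
failures concentrate.

`prior_sd = "auto"` (the default) moment-matches the prior variance as the
mean over all unordered pairwise contrasts and tested genes of
$\max(b^2 - \mathrm{se}^2, 0)$, floored at $0.05^2$ — an estimate of the
spread of true effects. It is computed once per dataset from the first fit's
full set of pairwise contrasts, so it is invariant to the parameterization
and shared across the reference-swapped refits; during development,
per-reference estimation was found to manufacture discordance at every
expression level purely from asymmetries in the estimated scales. Genes
whose noisy contrasts carry no detectable excess signal dilute the mean, so
a large sparse fraction tightens everyone's shrinkage — and prefiltering
relaxes it. Out-of-scope estimators (apeglm's adaptive Cauchy, ashr's
mixture priors) can be plugged in through
`register_shrinkage_backend()`; the package validates only the returned
schema.

## Mirror diagnostics

For each unordered pair of groups, the forward direction is the
alphabetically later test level unless the caller overrides it. DEGs are
classified by *membership*: concordant if in both reciprocal DEG lists,
discordant otherwise. Concordance deliberately ignores sign opposition —
concordant genes whose directions do not oppose are counted separately as
sign violations and warned about, and the per-gene sum
$\mathrm{LFC}_{fwd} + \mathrm{LFC}_{rev}$ (zero under exact mirroring) is the
quantitative instrument for such distortions. The discordance percentage is
$100\,(1 - |\mathrm{concordant}| / |\mathrm{union}|)$, pinned to 0 for an
empty union; the union convention is the only one under which the stacked
bar chart's three segments sum to its total. The percentage change in
concordant DEGs after cleaning, $100\,(\mathrm{after} -
\mathrm{before})/\mathrm{before}$, is flagged undefined when the baseline is
zero rather than propagating an infinity.

The expression-split diagnostic groups $\log_{10}$ baseMean (the mean of
normalized counts across *all* samples, identical in every contrast of a
dataset) by category and reports a global Kruskal–Wallis p plus uncorrected
pairwise Wilcoxon p-values — uncorrected because each pair is annotated
individually, and fewer than two nonempty categories yields a flagged
undefined rather than an error. Exclusive (UpSet-style) intersections
partition the union of any named gene sets; every gene belongs to exactly
one membership pattern, sizes are ordered descending with name tie-break,
and the detail CSV lists one gene per row with its memberships.

## Data cleaning

**Prefiltering** re-implements the published default low-count rule: with
$n$ the smallest group size (damped above 10 to $10 + 0.7(n-10)$), keep
genes whose counts-per-million exceed $10^7/\mathrm{median\ library\ size}$
in at least $n$ samples and whose total count is at least 15. It is
deterministic, idempotent, and order-invariant, and the test suite holds it
equal to an independent implementation of the same published rule on
hundreds of random matrices.

**Surrogate variables** are estimated by a deliberately simplified two-step
procedure — *not* the iteratively reweighted original: regress
$\log_2(\mathrm{normalized\ count}+1)$ on the known design, take principal
components of the residuals, and choose how many to keep by a permutation
test on eigenvalue *proportions* (each gene's residuals permuted
independently, re-residualized on the design so matrix ranks match, p-values
monotonized down the scree; $B = 100$, level 0.05, seeded). Proportions
rather than raw eigenvalues matter: permutation re-residualization shrinks
total variance, and comparing raw eigenvalues systematically over-selects.
The simple $\log_2(x+1)$ transform is pinned in place of a
variance-stabilizing transform so the stage has no library internals in its
definition. A full SVA implementation can be substituted upstream simply by
merging its surrogate variables into the sample table as covariates.

## The simulator

`simulate_dataset()` draws $K_{gj} \sim \mathrm{NB}(L_j B_{gj} q_g
2^{e_{g,\mathrm{group}(j)}}, \alpha_g)$ with log-normal baselines $q_g$,
log-normal library factors $L_j$, log2-additive group effects (zero-inflated
two-sided log-normal magnitudes, random sign), an optional hidden batch
multiplier, and — importantly — per-gene dispersion drawn around the
canonical decreasing trend $a_0 + a_1/q_g$ with log-normal noise, so
low-count genes are intrinsically noisier as in real RNA-seq. Without that
mean–dispersion coupling, high-dispersion genes appear at all expression
levels and discordance fails to concentrate at low expression, which is
where it is observed in practice. Effect magnitudes default to median
$3$ on the log2 scale (sd 0.5 on the log): strong, well-separated effects
typical of severe-disease-versus-control comparisons, which keep DEG counts
per contrast in the tens to hundreds at the default thresholds and 2000-gene
scale. All randomness flows from one mandatory seed through three fixed
streams (gene-level, sample-level, count noise), so partial re-simulation is
stable and equal seeds give bit-identical outputs.

Three presets encode the archetypes the diagnostics are aimed at:

* `cellline` — six groups of 3, dispersion asymptote 0.01, 5% sparse genes:
  tight in-vitro replicates. Concordance is excellent without any cleaning
  (mean discordance around 1–2%), though exact zeros in every pair are not
  guaranteed: under a normal prior each pair retains a thin shell of
  borderline DEGs.
* `clinical` — four unequal groups (6/8/7/5), dispersion asymptote 0.2 with
  a strong low-count limb (upper tail around 2), 30% sparse genes with
  doubled dispersion: noisy patient cohorts where the mirror check fails
  before cleaning and prefiltering reduces discordance.
* `batch` — the clinical scenario plus a strong hidden 2-level batch
  (30% of genes, typical fold $2^{1.5}$) partially confounded with the
  groups (batch-1 share 0.8/0.65/0.35/0.2 across severity, as when cohorts
  are collected over time): hidden structure biases contrasts, and
  surrogate-variable adjustment — not prefiltering — is the cleaning step
  that addresses the cause. With a batch balanced within groups no contrast
  is biased, which is why the confounded design defines this archetype;
  the orthogonal variant remains available (and is what the SV-recovery
  tests use) by omitting `group_props`.

What the simulator does *not* emulate: correlated effect structure across
groups (each group's effects are independent, so between-group variance
spreads over $k-1$ principal axes rather than concentrating in PC1 as
replicated treatment axes do), gene–gene correlation, GC/length biases,
outlier samples, and single-cell zero inflation. Passing tests on these
simulations therefore demonstrate the *mechanisms* — mirror symmetry and its
shrinkage-induced failure, rescue by cleaning — not performance on any
particular real dataset.

## Numerical choices and degenerate inputs

* Counts within $10^{-6}$ of an integer are rounded; anything else is
  rejected with the gene and sample named, as are negative values and
  duplicate IDs.
* Ranked `.rnk` exports sort by LFC descending with lexicographic gene-ID
  tie-break, drop missing LFCs with a logged count, and always export the
  full unthresholded list.
* Tabular outputs print numerics as `%.15g` and missing values as `NA`, so
  round-trips preserve at least 12 significant digits and re-runs diff
  cleanly.
* An empty DEG set, an empty prefilter result, or an empty plot input are
  valid (plots annotate "0"), and an empty union defines discordance 0.
* The test suite and the reproduction script run the full pipeline at 2000
  genes and 15–26 samples per scenario, with 100–500 replicates for the
  oracle and calibration checks — sizes chosen so every mechanism is
  exercised at the scale where it appears while a complete run stays fast on
  a laptop.

## Known limitations

* The built-in ridge estimator reproduces the *existence* and the
  low-expression concentration of reference-dependence, but a zero-centered
  normal MAP also has an irreducible borderline shell from the joint-penalty
  geometry. Prefiltering therefore shifts only a minority of surviving
  discordant genes into the concordant set here (the larger share of its
  benefit is removing discordance-prone genes), whereas estimators that
  re-learn a heavy-tailed prior per fit can show wholesale shifts. Plug such
  an estimator in via the backend hook to study it.
* Likewise, surrogate-variable adjustment reliably removes the
  confounding-driven part of discordance (and recovers the most concordant
  DEGs of any strategy on the batch archetype), but whether it beats
  prefiltering on the raw discordant count is a near-tie that can go either
  way between simulated datasets.
* The Wald test with a normal reference is anti-conservative at very small
  group sizes; interval coverage is validated (90–98% nominal 95%) at
  $n = 10$ per group on high-count genes, not at $n = 3$.
* Graphics are written as PNG only; the diagnostic values on every plot are
  echoed in the returned artifact so they can be checked against the tables
  without parsing images.
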