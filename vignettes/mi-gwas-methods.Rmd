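---
title: "Methods: multiple-imputation GWAS for low-depth GBS panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple-imputation GWAS for low-depth GBS panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genotyping-by-sequencing (GBS) at very low depth produces SNP panels in
which most genotype calls are missing — often around three quarters of
all cells — with a wide spread of per-marker missing rates. Discarding
incomplete markers wastes most of the panel; single imputation treats
guessed genotypes as data and overstates confidence. `migwas` implements
the alternative: *multiple imputation* (MI) of the dosage matrix, mixed-model
association testing on each completed copy, and pooling of the
per-impute estimates so that imputation uncertainty propagates into the
final p-values.

Dosages are coded -1 (reference homozygote), 0 (heterozygote), +1
(alternate homozygote) under assumed disomic inheritance, with missing
calls as `NA`.

## Marker quality control

Three filters run in order (`run_qc()`), each with a strict `<`
threshold:

1. **Per-panel PMV**: a marker is kept only if its proportion of missing
   values is below 0.90 in *every* panel. The default is deliberately
   lenient: high-PMV markers are exactly where MI earns its keep, and the
   pipeline's diagnostics are designed to show how far they can be
   trusted.
2. **Constant / collinear**: markers with observed variance at most
   `var_eps` (default 1e-12; "close to zero" is not otherwise
   quantified) are dropped, then any marker correlated at `|r| >= 0.999`
   (pairwise-complete) with a better-observed marker is dropped. Near
   duplicates would otherwise both inflate the multiple-testing burden
   on effectively one test and let chained imputation copy a variable
   into itself, understating uncertainty. Correlations use
   pairwise-complete observations, pairs with fewer than 3 overlapping
   calls are not compared, and the scan is a greedy pass in
   ascending-missingness order with ties broken by column index — a
   documented choice; the pair-resolution order is otherwise arbitrary,
   and this one is deterministic and keeps the "fewest missing values"
   member of each pair.
3. **MAF**: markers with observed minor allele frequency below 0.05 in
   the analysis subset are dropped (allele counts from observed calls
   only).

The filters are idempotent, and the QC report partitions the input
markers exactly (audit property, tested).

## Multiple imputation by chained classification trees

`fcs_impute()` samples the missing cells from their joint predictive
distribution by fully conditional specification — a pseudo-Gibbs sampler
that cycles over markers, re-drawing each marker's missing cells from a
model of that marker given all the others. The per-marker conditional
model is a classification tree (CART, Gini splits, via rpart) over the
three dosage classes:

* **Initialization**: each chain fills every marker's missing cells by
  marginal draws from that marker's observed values (ties among equally
  frequent values need no special handling — draws are uniform over
  observed calls).
* **Sweeps**: `L = 10` full passes; within a sweep, marker *k*'s tree is
  fitted on its observed rows using the current values of its
  predictors (already-updated for markers visited earlier in the sweep,
  previous-sweep values otherwise) and its missing rows are routed down
  the tree.
* **Donor draw**: an imputed cell is drawn uniformly from the observed
  target values ("donors") in its terminal node. The implementation
  draws a class from the leaf's class proportions, which is the same
  distribution. Trees are grown with at least `min_leaf = 5` donors per
  leaf and no further cost-complexity pruning, so leaves stay large
  enough to represent genuine conditional variability.
* **Predictor preselection**: for each marker only the `qsel = 500`
  markers with the highest marginal mutual information (bits, from
  pairwise-complete observed data, computed once before any chain) are
  candidate predictors; ties break by marker index. Rankings are fixed
  across chains.
* **Visit order**: sweeps visit markers in ascending missingness by
  default (better-observed markers stabilize first); this is
  configurable, as the order within a sweep is otherwise a free choice.
* **Reproducibility**: one master seed spawns a deterministic child
  stream per chain, so chains are independent and could run in
  parallel. (We seed per chain rather than per chain-sweep-marker; the
  chain is the parallelisation unit, and within a chain the sweep is
  inherently serial.)

`m = 20` chains yield the impute set; `average_dosage()` gives the
average-dosage (AD) matrix, whose cells are means over imputes (observed
cells are untouched everywhere, an invariant asserted cell-wise in the
tests). The defaults `m = 20`, `L = 10`, `qsel = 500`, `min_leaf = 5`
are the tool's standard operating point; all are configurable.

The sampler's identifying assumption is *missingness completely at
random* (MCAR): read dropout at a marker does not depend on the
genotype or the trait. Under MCAR the complete-case estimate is
unbiased, which is what makes the CC scheme the reference for the bias
diagnostics below. The synthetic generator also has strict MCAR
masking, so mask-and-recover experiments are internally consistent.

## Association schemes

For trait vector `g` the mixed model is
`g = mu + x_k beta + Q v + u + e`, `u ~ N(0, K sigma_u^2)`,
`e ~ N(0, I sigma_e^2)`, with `Q` the first *t* PC score vectors of a
complete dosage matrix and `K` the VanRaden realized relationship
matrix `W W' / sum_j 2 p_j (1 - p_j)`. Variance components are
estimated once by REML under the null (no marker), profiling the
residual variance and optimizing the single variance ratio on the
spectral decomposition of `K`; per-marker tests then hold the ratio
fixed (the P3D approximation) and reduce to OLS on decorrelated data,
with the residual scale re-estimated per marker and a 1-df F-test on
`n - 2 - t` denominator degrees of freedom. Holding the *ratio* (not
the absolute variances) fixed makes the `sigma_u^2 = 0` limit collapse
exactly to ordinary least squares, which the tests assert against a
hand-computed OLS fit.

Four schemes (`run_scheme()`):

* **CC** — complete cases: each marker tested on its observed rows
  only, with `Q`/`K` from the AD matrix held fixed (subset to those
  rows) and the full-panel variance ratio reused. Whether the original
  analyses re-estimated variance components per marker subset is
  ambiguous; we reuse the full-panel ratio, which is the natural P3D
  reading and is documented here.
* **AD** — the AD matrix as fixed dosages; one null fit.
* **MI** — each impute scanned with `Q`/`K` fixed; the AD null fit is
  reused across imputes.
* **MI\*** — each impute scanned with its *own* `Q`, `K` and null REML
  fit, so uncertainty in the structure estimates propagates too. This
  matters: on high-missingness panels the kinship matrix is stable
  across imputes but trailing PCs are not (see `consistency()` and the
  Stage-4 analysis script).

With no `Q` and no `K` (biparental populations) the model degenerates
exactly to single-marker regression.

## Pooling, gamma, and FDR

`pool_estimates()` combines the `m` per-impute estimates by Rubin's
rules: pooled effect `beta_bar`, within-impute variance `W_bar`,
among-impute variance `B* = (m+1)/m Var_r(beta)`, total `T = W_bar +
B*`, and the pooled test `p = Pr(F(1, v) > beta_bar^2 / T)` with the
Barnard-Rubin degrees of freedom `v = v_m v_obs / (v_m + v_obs)`,
`v_m = (m-1)/lambda^2`, `v_obs = (v_com+1)/(v_com+3) v_com (1-lambda)`,
`v_com = n - (2 + t)`. The fraction of information about the effect
lost to missingness is `gamma = (s + 2/(v+3)) / (1+s)`, `s = B*/W_bar`;
it behaves as `lambda = B*/T` adjusted for finite `m` (on our synthetic
scans the no-intercept slope of gamma on lambda is ~1.01-1.03 with
R^2 > 0.99). `B* = 0` is handled analytically (`lambda = 0`,
`v = v_obs`) rather than through infinite intermediate values. Gamma
classes: below 0.2 "modest", 0.2-0.3 "moderately large", 0.3-0.5
"high"; we extend the published classes with "extreme" for gamma >=
0.5, which low-depth GBS panels reach routinely.

FDR control uses Storey q-values with the smoother pi0 estimate
(`pi0(l) = mean(p > l)/(1-l)` on the grid 0.05-0.95, cubic smoothing
spline with 3 df evaluated at the last grid point); associations with
q < 0.1 are flagged. FDR is computed within trait. A genome-wide
Bonferroni threshold (`alpha / n_tests`) is provided for single-trait
reference lines.

## Diagnostics

* `consistency_regression(..., "cc_on_ad")`: CC effects on AD effects.
  Slope 1 and a null intercept indicate no imputation bias (the MCAR
  argument above); stratifying at gamma = 0.2 shows the residual
  variance inflating where imputation uncertainty is high. The
  regression uses unstandardised estimates — standardising both sides
  would force the slope to equal the correlation and mask the bias
  check; `standardize_by_trait()` exists for cross-trait concordance
  plots, not for this regression. One behaviour worth knowing when
  reading this diagnostic: the AD matrix is a finite-`m` average, so
  its cells retain classical measurement noise of order
  (among-impute variance)/m. Where a *strong true effect* coincides
  with *high missingness* this attenuates the AD estimate by a few
  percent and pushes the CC-on-AD slope slightly above 1; over null
  markers the slope sits at 1 as theory predicts. On panels whose
  detectable effects live at well-observed markers the attenuation is
  invisible.
* `consistency_regression(..., "ad_on_mi")`: AD on pooled-MI effects
  with a gamma interaction; `b1 = 1` (agreement at gamma 0) and
  `b3 > 0` (shrinkage of uncertain effects) are the expected pattern,
  and the generative-recovery test confirms the fit recovers both when
  data are built from the linear model. On pipeline output, though,
  the true shrinkage multiplier is *convex* in gamma (roughly
  `1/(1 - lambda)`): per-impute dosage draws carry classical error that
  attenuates each per-impute estimate, increasingly so as gamma grows.
  A single line `b1 + b3 gamma` fitted through a gamma distribution
  concentrated at 0.3-0.6 — which is where a 78%-missing panel lives —
  places its intercept well below 1 even though the gamma-binned
  slopes do approach 1 as gamma approaches 0. The sign of `b3` is the
  robust, portable conclusion; the fitted `b1` is a property of the
  panel's gamma distribution as much as of the method.
* `gamma_factor_model()`: OLS of `arcsin(gamma)` on PMV, MAF and AMI
  (average mutual information with the rest of the panel,
  `average_mutual_information()`), with 10-fold CV r^2 and MSE against
  the intercept-only null; folds are seeded and stratified by PMV decile
  so each fold sees the whole missingness range. The transform is
  `arcsin(gamma)` as such, not `arcsin(sqrt(gamma))`; the variance-
  stabilising square-root variant is noted here as the common
  alternative. Expected signs: PMV increases gamma, AMI decreases it.
  Residuals are heteroscedastic in gamma; OLS standard errors are
  reported regardless, and should be read as descriptive. Note that
  empirical MI on pairwise-complete data has an upward small-sample
  bias that grows as overlap shrinks, i.e. with PMV; AMI is therefore a
  noisy, slightly PMV-confounded proxy on very sparse panels.
* `delta_significance()`: per-association change in -log10(p) between
  two scans, summarized in the gamma < 0.2 / >= 0.2 strata — the "gain
  regime" lives almost entirely below 0.2.
* `pairwise_r2()`: squared Pearson correlation of AD dosages as the LD
  proxy among significant markers (no map is assumed), with the
  standard correlation t-test per pair.

## The synthetic generator

`sim_config()` / `simulate_panel()` generate the study conditions every
test runs under:

* **Structure**: a Balding-Nichols model — ancestral allele frequencies
  uniform on (0.1, 0.9), so the expected MAF is 0.30, and subpopulation
  frequencies Beta-dispersed at the configured Fst (default 0.1, 3
  subpopulations).
* **LD**: markers come in blocks (default 5); non-founder markers copy
  the block founder's dosage and redraw cells with probability
  `1 - block_r`, giving founder-copy correlation ~`block_r` without
  needing marker order or a recombination map. `block_r` may vary by
  block: heterogeneous LD is what gives the AMI covariate genuine
  signal in the gamma factor model; a constant-LD panel cannot
  identify it.
* **Missingness**: per-marker PMV is drawn from a two-component scaled
  beta mixture with mean exactly 0.78 and support [0, 0.9) — a small
  well-covered component (weight 0.1) and a dominant high-missingness
  component — then cells are masked uniformly (strict MCAR). PMV and
  MAF are drawn independently; the joint behaviour of the two in real
  GBS panels is not characterised well enough to commit to more.
* **Traits**: `g = mu + sum x_j beta_j + u + e` with `u ~ N(0, var_u
  K)` computed from the complete genotypes (diagonal jitter 1e-8 if the
  Cholesky fails) and iid residuals.
* **Seeding**: one master seed spawns child streams per stage
  (genotypes, causal draw, polygenic effects, residuals, mask), so any
  stage can be re-run identically in isolation.

What the generator does *not* emulate: coalescent genealogies,
recombination maps, genotype-calling error (heterozygote undercalling
at low depth), allele-frequency-dependent missingness, or polyploid
dosage. Passing tests therefore demonstrate the statistical machinery
under clean MCAR, HWE, disomic conditions — not robustness to calling
error or to missingness that depends on genotype. An MAR-violation
toggle was considered and deliberately left out of the generator
defaults; robustness experiments belong in analysis scripts, not in the
study conditions.

## Numerical choices and problem sizes

* REML optimizes the log variance ratio on [-14, 14] with `optimize()`;
  a boundary optimum returns `sigma_u^2 = 0` with a warning; the
  residual variance is floored at 1e-8.
* Collinear markers (zero residual variance after projection) are
  flagged untestable per marker, never dropped silently.
* Zero p-values in significance differentials are clipped at the
  smallest representable double and flagged.
* The test suite's end-to-end studies are sized for a desk run: an
  uncertainty study of 550 individuals x 320 markers, 10 traits,
  m = 20, L = 10 (about 2,000+ marker-trait pairs), and a null study of
  300 individuals x 1000 independent markers, m = 5. The null study
  uses independent markers so the Kolmogorov-Smirnov uniformity check
  has its nominal level; with LD the test statistic's null distribution
  would be inflated. Predictor preselection in these studies uses
  qsel of 30-40 (the panels have at most a few hundred markers, and
  within-block signal saturates far below that); the package default
  remains 500.

## Known limitations

* The FCS sampler is a pseudo-Gibbs procedure: the per-marker
  conditionals are not guaranteed to cohere into a joint distribution.
  This is inherited from the method itself; burn-in adequacy is checked
  empirically (L = 10 vs 20 is indistinguishable on the test panels).
* Confidence validity of the imputations (among-impute variance
  matching what complete data would give) is assumed, not tested; only
  unbiasedness has a direct diagnostic (the CC-on-AD regression).
* CC tests on very sparse markers rest on few individuals and are
  noisy; the pipeline reports `n_used` so downstream filtering is
  possible.
* Empirical MI scores on nearly disjoint observation sets are biased
  upward; predictor rankings for ultra-sparse marker pairs are
  correspondingly noisy.
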