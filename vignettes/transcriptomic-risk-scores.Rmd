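---
title: "Transcriptomic risk scores: methods and design"
author: "trscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic risk scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trscore)
```

## The model

A transcriptomic risk score (TRS) aggregates observed gene expression into
a single per-individual burden, using gene-level results of a
transcriptome-wide association study (TWAS) as weights. For individual
$i$ and a gene set $G$ selected from one expression reference panel
(tissue),

$$\mathrm{TRS}_i = \sum_{g \in G} z_g \, x_{ig},$$

where $z_g$ is the signed TWAS Z-score of gene $g$ in that panel and
$x_{ig}$ is the individual's expression of $g$, standardized gene-wise to
mean 0 and sample standard deviation 1 ($n-1$ denominator). The sign of
$z_g$ carries the predicted direction of effect, so concordant
up- and down-regulation both push the score in the risk direction.

Gene sets are chosen by a fixed ladder of TWAS p-value thresholds
(`trsThresholdLadder()`): the per-panel Bonferroni level
$\alpha / m_\text{panel}$ and the nominal levels 0.001, 0.05, 0.1, 0.2,
0.3, 0.4, 0.5 and 1. Each panel is corrected for its own number of genes
tested, since panels differ substantially in gene content.

Association with a binary phenotype is tested by maximum-likelihood
logistic regression of case status on the TRS with covariates (sex, age,
genotyping wave and 10 genetic principal components by default, matching
the usual confounder set for a genotyped case-control expression cohort).
The TRS is divided by its own sample SD before regression so estimates
are per-SD log-odds ratios comparable across tissues; the raw weighted
sums are also available (`computeTrs()` returns them). Whether the source
analyses standardized the score before regression is generally not
reported; per-SD scaling is our choice and is consistent with per-SD
effect sizes in the 0.2--0.45 range typically reported for such scores.

### Threshold scan and the permutation null

The best threshold per tissue is the one with the smallest score Wald
p-value (`bestThresholdScan()`; ties go to the smaller gene set). Taking
a minimum over a ladder of correlated tests overfits: the naive minimum
p-value is anti-conservative. The empirical p-value
(`empiricalPvalue()`) therefore permutes the phenotype $B$ times
(10,000 by default), repeats the *entire* threshold scan within each
permutation, and compares the observed minimum against the permuted
minima:

$$p_\text{emp} = \frac{r + 1}{B + 1}, \qquad
r = \#\{b : \min_t p^{(b)}_t \le \min_t p^\text{obs}_t\}.$$

The smallest attainable value is $1/(B+1)$ ($9.999\times 10^{-5}$ at
$B = 10{,}000$). Covariates stay attached to their samples; only the
phenotype labels move. This is a simple-permutation null: it deliberately
breaks any covariate-phenotype linkage, which is the standard choice for
this design and is acknowledged as an approximation when covariates are
strongly associated with the phenotype. A cheaper variant that re-tests
only the observed best threshold is available
(`scanPerPermutation = FALSE`) but is anti-conservative; the test suite
demonstrates the difference under a simulated null.

Selections at different thresholds often resolve to identical gene sets
(e.g. Bonferroni and 0.001 in a small panel); the permutation engine
deduplicates them so each unique score is fitted once per permutation.

### Liability-scale variance explained

Logistic fits yield the Cox-Snell pseudo-$R^2$
$1 - \exp\{\tfrac{2}{n}(\ell_0 - \ell_1)\}$, an observed-scale quantity
that depends on the (ascertained) sample case proportion $P$. It is
converted to the liability scale at population prevalence $K$ (5% by
default) with the ascertainment-corrected transformation: writing
$t = \Phi^{-1}(1-K)$, $z = \varphi(t)$, $m = z/K$,

$$C = \frac{K(1-K)}{z^2}\cdot\frac{K(1-K)}{P(1-P)}, \qquad
\theta = m\,\frac{P-K}{1-K}\Bigl(m\,\frac{P-K}{1-K} - t\Bigr),$$

$$R^2_\text{liab} = \frac{C\,R^2_\text{CS}}{1 + C\,\theta\,R^2_\text{CS}}.$$

The full ascertainment form (with the $\theta$ curvature term) is
implemented; at $K = P$ it reduces to the simple linear scaling
$C\,R^2_\text{CS}$. The reported quantity is the *increment*
attributable to the score: the liability-scale $R^2$ of the
covariates-plus-score model minus that of the covariates-only model, both
measured against the intercept-only fit and transformed before
subtracting. The alternative (transform the Cox-Snell $R^2$ of full vs.
covariates-only directly) is available as `method = "direct"` in
`scoreIncrementR2()`; the two differ only at second order but the
convention should be stated, so it is.

### Sensitivity and colocalization variants

Because several genes in one region can sit under the same eQTL signal, a
locus-pruned score keeps one lead gene (smallest TWAS p; ties by smaller
TSS, then gene id) per locus. Loci are single-linkage chains of genes
whose TSSs lie at most 500 kb apart, never spanning chromosomes
(`clusterLoci()`, built on `GenomicRanges::reduce`). The source
convention is stated as "< 500 kb apart" joins and "> 500 kb apart"
separates, leaving exactly 500,000 bp unspecified; we merge at the
boundary (inclusive) and log when a pair sits exactly on it. Whether
distance should be TSS-to-TSS or boundary-to-boundary is likewise
unstated; TSS-to-TSS is used because the annotation consumed here carries
a single position per gene.

A colocalization-restricted score keeps only genes whose gene locus-level
colocalization probability (GLCP) in the scoring tissue is at least 0.5
(inclusive, `restrictColocalized()`); genes without a record are dropped.

### Multiplicity across tissues

Best-threshold TRSs from related tissues are strongly correlated, so a
Bonferroni correction over tissues is too harsh. The effective number of
independent tests is estimated from the eigenvalues $\lambda_j$ of the
TRS Pearson correlation matrix (Galwey's estimator):

$$M_\text{eff} = \frac{\bigl(\sum_j \sqrt{\lambda_j}\bigr)^2}{\sum_j \lambda_j},$$

with negative eigenvalues (possible for near-singular empirical matrices)
clamped to zero first — numerically safe and in line with the
estimator's published recommendation. The integer $M_\text{eff}$ is
rounded half away from zero (the rounding convention used to reach an
integer count is a choice; the unrounded value is kept alongside) and the
per-test significance level is the Sidak threshold
$1 - (1-\alpha)^{1/M_\text{eff}}$.

### PRS comparison and combination

The polygenic risk score arrives precomputed (one value per sample in the
cohort table). The package fits PRS-only, PRS+TRS and covariate-only
models with the same machinery, reports Pearson correlation between
scores (`trsPrsCorrelation()`, Bonferroni-corrected over reported pairs),
and compares nested fits with a chi-square likelihood-ratio test
(`lrtCompare()`; cross-checked against `lmtest::lrtest` in the test
suite). Quintile odds-ratio profiles (`quintileOddsRatios()`) rank
samples by score, split them into five equal-count bins (remainder to the
lower bins) and report Wald 95% intervals against the first quintile.

## Numerical choices

* Logistic fits use iteratively reweighted least squares with the same
  deviance-based convergence criterion as `stats::glm` (tolerance 1e-8,
  at most 100 iterations). The core is compiled (RcppArmadillo) because
  the permutation engine refits the scan thousands of times; agreement
  with `stats::glm` coefficients, standard errors and log-likelihoods is
  asserted in the test suite.
* Perfect or quasi-complete separation (any fitted probability within
  1e-8 of 0 or 1) and rank-deficient designs are explicit errors; the
  rank check names the collinear columns. Inside the permutation loop a
  failed fit contributes no minimum rather than aborting the scan.
* Standardization moments are taken over the full analysis sample (cases
  and controls jointly); this is the convention for observed-expression
  scores, where the score must be computable without knowing case
  status. Control-only moments are available
  (`standardizeExpression(..., controlOnly = TRUE)`).
* Zero-variance genes cannot be standardized and are an error naming the
  gene; missing expression values are rejected at read time (no
  imputation).
* All tables are TSV (tab-separated, header, UTF-8, "." decimal). Data
  tables round-trip at full double precision; derived result tables are
  written at 6 significant digits with p-values in scientific notation.
  Gene annotation is additionally accepted as BED (0-based half-open)
  and converted to 1-based TSS at read time.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; each synthetic-data generator draws from its own
  stream (base seed + fixed offset) so adding one generator never
  perturbs another.

## What the synthetic data emulate — and what they do not

The generator (`SimulationConfig()`, `simulateBundle()`) produces the
four inputs the pipeline consumes, with the statistical structure the
analysis assumes:

* **TWAS panels.** Per gene, Z-scores across tissues follow an
  equicorrelated multivariate normal (default pairwise $r = 0.98$,
  matching the near-duplication of gene-level results across related
  brain panels); causal genes get a shared signed mean shift
  (`twasEffect`, default 6, placing them clearly beyond a per-panel
  Bonferroni threshold at desk scale); p-values are the exact two-sided
  normal tail of the stored Z.
* **Expression.** Simulated directly on the standardized scale: controls
  i.i.d. standard normal per gene, cases shifted by a signed
  standardized mean difference (`exprEffect`, default 0.3) on causal
  genes, sign-matched to the TWAS Z except for an optional discordant
  fraction. No published scale exists for the observed-expression effect
  sizes; 0.3 with 5% causal genes is the calibration at which the
  pipeline's power properties were fixed before any acceptance run, and
  it is deliberately generous at desk scale.
* **Cohort.** 222 cases and 269 controls by design (ascertained
  sampling — precisely the situation the liability transformation
  corrects for; no explicit liability threshold model is simulated). Sex
  is frequency-matched near 57–59% male, age is drawn near 34–37 years
  with a small case deficit, two genotyping waves are sized roughly 1:2,
  and 10 genetic PCs are standard normal. The PRS is standard normal,
  shifted 0.33 SD in cases, and drawn independently of expression.
* **Colocalization.** GLCP from Beta(8, 2) for causal genes and
  Beta(2, 8) otherwise — bounded in [0, 1] with 98% of causal mass at
  or above the 0.5 cutoff.

What passing tests on these data do **not** show about real cohorts:
expression here has no correlation structure between genes (no
co-expression, no LD-induced redundancy within loci), no batch or
technical structure beyond the wave label, no confounding between
covariates and expression, and the TWAS weights are exactly normal with
known truth. In particular, with a shared causal architecture and
near-unit cross-tissue correlation, best-threshold TRSs from different
synthetic tissues are far more similar than real multi-tissue scores, so
the effective-number-of-tests estimate on fully default synthetic data
is much smaller than the 11-of-14 figure typical of real panels; the
multiplicity code is therefore additionally tested at low cross-tissue
correlation, where the estimate approaches the number of tissues.

## Problem sizes used by the checks

The test suite and the acceptance script scale the study down so the full
pipeline, including permutation nulls, runs comfortably on one CPU:
calibration of the scan-corrected empirical p uses 400 null replicates of
a 100-sample, 80-gene study at $B = 199$; power and independence checks
use 100–200 replicates of a 500-sample, 500-gene study; the end-to-end
acceptance run uses the full 14-tissue, 491-sample, 1000-gene default
with $B = 10{,}000$. These sizes are the package's own choices for a
reproducible desk-scale study.

## Known limitations

* Only binary phenotypes and unrelated samples; no mixed models,
  survival outcomes or continuous traits.
* The permutation null ignores covariate-phenotype linkage (see above).
* Gene identifiers are matched as literal strings between TWAS,
  expression and colocalization inputs; no symbol/accession translation
  is attempted, so the caller must supply consistent ids.
* The pipeline consumes TWAS summary statistics, GLCP values and PRS
  values as given; producing them (TWAS software, fine-mapping and
  colocalization, PRS posterior effects) is out of scope, as is any
  microarray preprocessing — expression is expected already
  batch-adjusted.
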