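---
title: "Random-forest genetic risk scores: models, tuning and simulation design"
author: "forestGRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest genetic risk scores: models, tuning and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A genetic risk score (GRS) summarizes an individual's genetic liability to a
binary trait from SNP genotypes $x_{im} \in \{0, 1, 2\}$ (minor-allele
counts). The classical clumping-and-thresholding score is additive,

$$\mathrm{GRS}_i = \sum_{m \in S} \hat\beta_m \, x_{im},$$

with $S$ the SNPs surviving LD clumping and p-value thresholding and
$\hat\beta_m$ marginal log-odds estimates. Additive scores cannot represent
epistasis — SNP–SNP interactions and other non-linear genotype effects.
forestGRS instead defines the GRS as a *forest-estimated disease
probability*: a random forest over the 3-level categorical genotypes (plus
covariates) is grown on the target training samples, each terminal node
stores its in-bag disease proportion, and a sample's GRS is the average
terminal proportion across trees (a "probability machine" — an ensemble
average of node-level class frequencies rather than a majority vote). The
probability average avoids the degenerate 0/1 scores a voting ensemble
produces when risk is strongly determined.

Two devices sharpen the forest:

* **ctRF** treats the LD-clumping $r^2$ cutoff and the p-value threshold as
  *hyperparameters of the forest pipeline*, tuned jointly with the usual
  forest settings (`ntree`, `mtry`, minimum node size) by grid search.
  Single-axis ablations (cRF: cutoff only; tRF: threshold only) and the
  unfiltered forest (oRF) are included for comparison.
* **wRF** keeps all SNPs but biases the `mtry` candidate draw at each split
  toward associated SNPs, using min–max-normalized association z-values
  $z_m = |\Phi^{-1}(p_m/2)|$,
  $w_m = (z_m - z_{\min})/(z_{\max} - z_{\min}) \in [0, 1]$.

Association p-values come either from the target training split alone
("Tonly": a Wald logistic-regression scan) or from external GWAS summary
statistics ("BT": base data harmonized to the target panel).

## Tuning objective

Each grid point selects SNPs (clump, then strict `p < threshold`), fits a
forest on the *full training split*, and scores the point by the Nagelkerke
pseudo-$R^2$ of the out-of-bag (OOB) GRS against the training outcome:

$$NR^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}},$$

with $L_1$ from the logistic regression of $y$ on the GRS (plus covariates
when present, in which case the null $L_0$ keeps the covariates). OOB
predictions — averages over only the trees whose bootstrap excluded the
sample — act as internal validation, so no inner cross-validation loop is
needed; samples that are in-bag for every tree are dropped from the
objective. Because forests at identical settings are re-grown from a seed
derived deterministically from those settings, the best tuning forest *is*
the final model: refitting it at the chosen point reproduces it bit for
bit, so the tuning-time forest is kept. Ties in the objective break toward
fewer retained SNPs, then fewer trees, then grid order.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| `r2_cutoffs` | 0.1, 0.2, 0.5, 0.8, 1 | squared Pearson correlation of allele counts, computed on training samples only; pairs with $r^2$ strictly above the cutoff are clumped. The value 1 removes nothing and is included so that the no-clumping ablations (tRF/oRF/wRF) are grid points of ctRF's search space, making ctRF's training objective provably $\ge$ cRF's and tRF's. |
| `p_thresholds` | $10^{-4}$ … 1 | strict `<`; 1 keeps SNPs with $p < 1$. |
| `window_bp` | 250,000 | clumping window, inclusive base-pair distance; a standard clumping convention. |
| `ntree` | 500 (200 in `deskGrid()`) | forest size. |
| `mtry` | $\lceil\sqrt M\rceil$, $\lceil M/10\rceil$, $\lceil M/3\rceil$ | per retained SNP count $M$; counts all features including covariates. |
| `min_node_size` | 1, 5, 10 | minimum samples in a node to attempt a split. |

Splits on SNPs are the three one-category-versus-rest partitions
({0} vs {1,2}, {1} vs {0,2}, {2} vs {0,1}), which span all binary
partitions of a 3-level factor without imposing an inheritance model;
covariates split at midpoints between distinct sorted values. The split
criterion is Gini impurity decrease, the standard classification default.
Equal-Gini ties resolve to the lowest feature index, then the lowest
partition index, making trees deterministic given the seed. Bootstrap
samples have size $n$, drawn with replacement. Weighted candidate sampling
draws `mtry` features sequentially without replacement with probability
proportional to the remaining weights; weight-0 features can never be
drawn, so the weakest SNP (weight exactly 0 under min–max scaling) is
excluded from splits — `weight_floor` lifts this if undesired. Covariates
receive the maximum SNP weight so they stay samplable; the weighting
scheme is defined for SNPs only.

## The synthetic cohort generator

The simulation engine emulates a chromosome-21-like SNP panel and five
causal architectures, at a desk scale of 1000 SNPs, 1000 target samples
and 2000 base samples by default (larger panels are supported).

**Genotypes.** Per block of 20 SNPs, a latent standard-normal AR(1) vector
with adjacent correlation $\rho = 0.7$ is thresholded at the
Hardy–Weinberg quantiles of a MAF drawn uniformly from (0.05, 0.30);
blocks are independent, positions are 5 kb apart. This yields blockwise LD
for clumping to remove, HWE-consistent genotype frequencies, and a
moderately rare spectrum. The MAF range is a deliberate compromise, chosen
once: the causal models below have no intercept and all-positive
interaction effects, so a common-heavy spectrum drives prevalence toward 1
and makes two-locus products mostly linear in the allele counts (an
additive score then captures them), while an all-rare spectrum makes
two-locus carrier pairs too scarce (< 1% of samples) for any method to
learn at 800 training samples. At (0.05, 0.30), roughly half of a typical
pair's variance is non-additive and carrier pairs occur in about 10% of
samples.

**Phenotypes.** 100 causal SNPs are drawn uniformly; effect sizes come
from Normal($\mu$, sd = 0.1) with exactly half of the main/quadratic
effects negated (within each half of the causal vector, so scenario 3's 50
main effects get exactly 25); interaction effects are left unflipped, as
sign-flipping is defined for main effects only. Scenarios: (1) 100
additive terms; (2) 100 two-way interaction terms pairing causal SNPs 1–50
with 51–100; (3) 50 additive + 100 two-way; (4) 30 three-way terms, one
SNP from each of three disjoint groups of 33 (the 100th causal SNP is
carried but inert); (5a/5b) 100 quadratic terms, 5b restricting the causal
pool to MAF > 0.3 so all three genotype classes are populated. Outcomes
are Bernoulli(expit($\eta$)). Defaults for $\mu$: log 1.5 for main and
quadratic effects, log 2 for interactions; the small-effect panels
(log 1.1, log 1.6) are available through `simConfig()`.

**Intercept.** The generating models have no intercept ($\beta_0 = 0$ by
default), so prevalence drifts as effects accumulate. The experiment
driver therefore centres each cohort's intercept at $-\bar\eta$
(`centerIntercept()`, `balance_prevalence = TRUE`) so that both outcome
classes stay well represented; single-model simulation functions leave
$\beta_0$ untouched unless asked.

**Base/target pairing.** The base cohort's architecture shares $q \in
\{100, 70, 50, 30\}$ causal SNPs with the target's; shared positions keep
the target's SNPs, and every term wholly inside the shared set keeps its
effect size bitwise. The remaining $100 - q$ base positions get fresh
SNPs, disjoint from all target causal SNPs, and terms touching them get
freshly drawn effects with the positional sign pattern retained. Base
summary statistics are produced by a marginal scan of the simulated base
cohort; only those statistics — never base individual-level data — enter
the GRS pipeline.

**What the generator does not emulate.** Realistic long-range LD,
population structure and admixture, genotyping error and missingness
patterns, and the empirical MAF spectrum of a real chromosome. Passing
tests therefore demonstrate correctness of the machinery and
reproducibility of the *relative* method behaviour under controlled
architectures, not absolute performance on real cohorts.

## Numerical and policy choices

* Monomorphic SNPs and non-converging or separating marginal fits are
  flagged and reported with $\beta = 0$, $p = 1$; a scan never aborts.
  Wald tests use the observed-information standard error, with no
  small-sample correction.
* p-values are kept in the open-closed interval $(0, 1]$ everywhere;
  underflowing scan p-values are clamped to the smallest positive double,
  and summary-statistics rows outside the interval are dropped with a
  reported count.
* Harmonization matches base to target by SNP id only; the base effect
  allele is aligned to the target minor allele (sign flip when it matches
  the major allele), unmatchable alleles are dropped and counted, and no
  strand-flip inference is attempted — strand-ambiguous A/T and C/G SNPs
  are matched by id like any other.
* Missing genotypes are not a fourth factor level: callers impute
  explicitly with `imputeMode()` (per-SNP modal count, ties to the smaller
  count) before scanning or forest fitting.
* Clumped SNPs removed by one index SNP never seed their own clump
  (PLINK's convention); p ties break by chromosome, position, id.
* In `nagelkerkeR2()`, a constant score returns exactly 0; fits whose
  probabilities touch 0/1 numerically are reported with a `separation`
  attribute, with likelihood contributions clamped at $10^{-12}$.
* AUC is the Mann–Whitney statistic with ties counted one half.
* Per-replication seeds derive from the master seed by a fixed counter
  stream, and per-grid-point forest seeds hash the settings, so every
  method sees identical data and removing a method from an experiment
  changes no other method's numbers.
* 5-fold cross-validation redraws folds stratified by outcome (logged)
  if a random fold lacks a class.

## Desk-scale problem sizes

The replicated experiments (`runExperiment()`, `deskGrid()`,
`scripts/acceptance.R`) default to 10 replications of 1000 SNPs, 1000
target and 2000 base samples, an 80/20 target split, 200 trees,
$\mathrm{mtry} = \lceil\sqrt M\rceil$, minimum node size 5, cutoffs
$\{0.1, 0.5, 1\}$ and thresholds $\{0.01, 0.1, 1\}$ — the package's chosen
desk-scale rendition of the full design (100 replications, a 10,330-SNP
panel, 500 trees and the full grid), which is also supported via
`simConfig()` and `hyperGrid()` for users with the patience for it.

## Known limitations

* Binary outcomes only; a continuous-trait forest (terminal-node means) is
  out of scope.
* No dosage/imputed genotypes, bgen, multi-allelic variants or liftover;
  reference-panel LD is not supported (LD always comes from target
  training genotypes).
* Variable-importance measures are deliberately not exposed: the
  probability-machine construction targets calibrated risk, and importance
  scores under strong LD are unstable and easy to over-interpret.
* The published joint-modelling and stacking baselines (penalized
  regression on all SNPs, stacked C+T, LDpred, lassosum and relatives) are
  comparators from the literature, not re-implemented here; oCT is the
  in-package additive baseline.
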