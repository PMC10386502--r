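---
title: "Multi-method metabolite prioritization: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-method metabolite prioritization: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarank)
```

## The problem

Untargeted metabolomics profiles tens of thousands of small-molecule
features per plasma sample, and clinical cohorts — especially for rare
diseases such as pulmonary arterial hypertension — are far smaller than
that. Any single feature-selection method applied to such data imposes its
own inductive bias: a univariate screen with multiple-testing correction
ranks each feature on its marginal association, so a block of mutually
correlated metabolites that shares one signal fills the top of the list
("convergent" selection); penalized regression or a decorrelating
discriminant score spreads credit across blocks and surfaces features from
orthogonal pathways ("divergent" selection). `metarank` implements six such
methods behind one ranking contract, aggregates their ranks, and quantifies
the intercorrelation structure of what each method selects, so that the
convergence/divergence behaviour of a method battery becomes a measurable
property rather than an anecdote.

## Preprocessing model

Raw intensities are assumed strictly positive with multiplicative noise and
batch-level location/scale artifacts, hence the fixed order:

1. **log transform** (natural log; the base only rescales coefficients,
   never ranks);
2. **per-batch median/MAD normalization**: within each batch every feature
   is centred at its batch median and divided by its batch MAD scaled by
   1.4826. The consistency constant puts the MAD on the SD scale, the
   conventional reading of "median absolute deviation" as a robust scale
   estimate. A zero batch MAD falls back to the feature's global MAD (with
   a warning); a feature degenerate everywhere becomes a zero column and is
   flagged rather than dropped, keeping column indices stable across
   methods;
3. **feature scaling** to mean 0, SD 1 (n−1 denominator), applied globally
   rather than per outcome group — the outcome should not leak into the
   transformation. Scaling is idempotent to ~1e−12.

## The six ranking methods and their contracts

Every method emits a `method_ranking`: per-feature score, integer rank
(1 = most important) and an imputation flag. Features a method does not
score — a zero LASSO coefficient, a feature unused by the boosted trees, a
failed univariate fit — all receive the *total feature count* as their
rank. This single imputation constant is what makes sparse and dense
selectors commensurable during aggregation; the alternative (mid-rank of
the unselected set) would systematically reward sparse methods, so the
literal constant is used.

- **Univariate logistic screen** (`rank_univariate`): per feature,
  `outcome ~ feature + age + sex` by maximum likelihood; Wald p-values (the
  conventional default for per-feature GLM screens). Bonferroni
  (`min(1, m·p)`) and Benjamini–Hochberg step-up adjustments are tabulated
  as *two* methods since they answer different error-rate questions.
  Ties in adjusted p break by raw p, then feature id, so reruns are
  bit-identical. The BH step-up is written out directly so the adjusted
  values match the canonical formula bit for bit.
- **LASSO / elastic net** (`fit_lasso_cv`, `fit_elastic_net_cv`): glmnet
  logistic fits; 10-fold outcome-stratified, seeded cross-validation
  minimizing binomial deviance; lambda grid of 100 log-spaced points down
  to 1e−3 of the analytic lambda-max; elastic-net alpha grid 0.1…1.0 with
  the fold assignment held fixed across alpha so errors are comparable.
  Age and sex enter unpenalized (mirroring the univariate adjustment — the
  most defensible default, switchable via `adjust_covariates = FALSE`) and
  are excluded from the ranking. Alpha = 0 is excluded: ridge never
  produces exact zeros, so rank-by-|coefficient| would never impute and the
  selection behaviour being studied would disappear.
- **Random forest** (`tune_and_fit_forest`): `mtry`/`nodesize` tuned by OOB
  misclassification (ties toward the more regularized pair), then refit
  with OOB permutation importance. Importance is the primary ranking score;
  average minimal depth — computed in-package by walking each tree — breaks
  ties and optionally gates selection at the forest-average depth. Both
  orderings are exposed because accuracy-based importance and minimal-depth
  selection are distinct conventions; importance is the default.
- **Shrinkage discriminant analysis** (`catscore_fit`): correlation-adjusted
  t-scores `cat = R*^{-1/2} t`, with `t` the studentized group-mean
  difference using variances shrunk toward their median and
  `R* = λI + (1−λ)R` the pooled within-group correlation matrix shrunk
  toward the identity with the analytic (Ledoit–Wolf/Schäfer–Strimmer)
  intensity. On null data the analytic λ approaches 1 (all observed
  correlation is noise, so full shrinkage is risk-minimizing) and CAT
  collapses to t; with real block correlation λ is small and the
  inverse square root decorrelates the evidence, which is exactly why CAT
  top lists are divergent. For large p the inverse square root is never
  formed densely: R* is identity-plus-low-rank, so a thin SVD of the
  group-centred data gives the scores in O(n²p); the low-rank route is
  validated against a dense eigendecomposition oracle to 1e−8. For two
  balanced groups, ranking by group-vs-group CAT and by per-group-vs-pooled
  centroid scores coincide up to a constant, so the group-vs-group form is
  implemented.
- **Gradient boosting** (`tune_and_fit_xgb`): logistic-loss XGBoost;
  (max_depth, learning rate) grid scored by 5-fold CV classification error
  with early stopping; single-threaded and seeded so reruns are identical.
  Features are ranked by fractional total gain (gains sum to 1 over used
  features); unused features are imputed.

## Aggregation and the convergence diagnostic

With the imputed feature × method rank matrix in hand, three row statistics
summarize cross-method behaviour: the **integrated rank** (sum — low means
consistently prioritized), the **difference rank** (max − min — the widest
disagreement), and the **variance rank** (sample variance, n−1). Reporting
typically focuses on the best few hundred features by integrated rank
(`focus_top`).

For each method, the top-50 features' pairwise Pearson correlations (on the
preprocessed matrix) are summarized two ways, because "x% of the top 50
were highly correlated" is ambiguous: the share of *pairs* with |R| at or
above 0.4, and the share of *features* participating in at least one such
pair. Both are reported; the convergent/divergent label uses feature
participation (the more literal reading) against a 0.5 threshold, boundary
inclusive. The 0.4 cut-off is the conventional lower edge of "moderate"
correlation and is configurable (`high_threshold`), as published analyses
have used 0.3 for tree ensembles and 0.4 for p-value rankings without
reconciling the two.

## The synthetic cohort generator

`simulate_metabolome` is a first-class module, not a fixture: it encodes
the statistical structure the analysis assumes so every downstream claim is
testable without patient data.

- **Correlation**: features come in blocks; within a block, log intensities
  are equicorrelated via a one-factor construction
  `sqrt(rho)·z_block + sqrt(1−rho)·e` (an AR(1) option is available). The
  default 20 blocks × 25 features at rho = 0.7 gives p = 500 — large enough
  for p ≈ n behaviour and strong block structure, small enough that the
  whole battery runs in minutes on one CPU.
- **Outcome**: logistic in the *first feature of each signal block*
  (standardized log scale; default 5 blocks at 1 log-odds per SD), plus age
  and sex terms. One causal feature per block, with its 24 block-mates
  associated only through correlation, is precisely the structure on which
  convergent and divergent selectors must disagree.
- **Cohort marginals**: age ~ Normal(52, 18) truncated to [18, 95], 78%
  female, intercept centred so the case fraction is near 0.43 — matching a
  published idiopathic-vs-other pulmonary arterial hypertension case mix so
  synthetic cohort tables are comparable to printed ones.
- **Batches**: 4 batches with additive per-(batch, feature) log-scale
  shifts (SD 0.3), which the median/MAD normalization must remove.
- **Determinism**: a single seed (default 20230628) drives every draw;
  identical configs reproduce datasets bit for bit.

What the generator does *not* emulate: missing intensities, heavy-tailed
or non-Gaussian noise, injection-order drift, annotation/chemical identity,
and correlation between blocks. Passing tests therefore demonstrate the
methods' behaviour under clean block-equicorrelated Gaussian structure, not
robustness to real-data pathologies.

## Numerical choices and degenerate inputs

- Eigenvalues are floored at 1e−12 in the dense inverse square root; the
  low-rank route requires λ ≥ 1e−8 and falls back to the dense path below
  that.
- Exact rank ties anywhere resolve by feature id, making every ranking
  deterministic.
- Perfect separation in a univariate fit is flagged (fitted probabilities
  at the boundary) and the Wald p is still reported; non-converged or
  rank-deficient fits are scored missing and rank-imputed.
- Zero-variance features are carried as flagged zero columns through every
  stage and receive correlation 0 in the diagnostic matrices.
- Tuning ties: forest (smaller `mtry`, then larger `nodesize`), boosting
  (shallower trees, then slower learning), elastic net (larger alpha) —
  always toward the more regularized model.
- L1 active sets are not nested along the lambda path: a variable can drop
  out as a correlated partner enters. The path diagnostics therefore check
  a strongly increasing trend rather than strict monotonicity.

## Problem sizes used in the shipped checks

The test battery exercises the generator at its default study conditions:
the convergence contrast on 20 cohorts of n = 500 (FDR-ranked top-50 pair
fractions ≈ 0.29 versus ≈ 0.06 under CAT and ≈ 0.07 under LASSO), causal
recovery on 20 cohorts of n = 1000 (all five planted features in every
method's top 50 in ≥ 80% of replicates), and null calibration on cohorts
with no feature effect. Forest and boosting checks use single-point tuning
grids and 150–200 trees at these sizes; the full grids remain the defaults
for real analyses.

## Known limitations

- **Null selection is itself convergent for p-value rankings.** Because
  test statistics of correlated features are correlated, the 50 smallest
  p-values out of 500 preferentially come from blocks whose shared factor
  chance-correlated with the outcome — even under a global null, where the
  FDR top-50 pair fraction (~0.1–0.25) sits far above the ~0.05 of random
  50-feature draws. Convergence of a p-value ranking is therefore partly a
  selection artifact, and comparisons of top-k intercorrelation are only
  meaningful *between* methods on the same data, not against a
  random-draw baseline.
- At the default synthetic scale — 50 picks from 500 features of which a
  quarter are block-correlated — the *participation* statistic saturates
  (most top-50 features touch at least one high pair), so most methods earn
  the convergent label and the pairwise fraction is the discriminating
  statistic. At the ~50,000-feature scale the diagnostic was designed for,
  divergent selectors draw mostly from uncorrelated features and
  participation separates methods as intended.
- Per-dataset null p-value fractions are overdispersed relative to the
  binomial (blocks act as ~20 effective units, not 500), so calibration
  statements average over replicate cohorts.
- The forest permutation importance relies on the engine's internal OOB
  permutation; it is seeded and reproducible but not exposed as a
  standalone re-runnable permutation.
- The cohort table handles one binary outcome and flat covariates; no
  survival or repeated-measures support is intended.
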