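---
title: "Discriminating vascular MCI from cognitively normal SVD with nested lasso selection and sparse logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating vascular MCI from cognitively normal SVD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestedSLR)
```

## The problem

Cerebral small-vessel disease (SVD) produces diffuse white-matter injury and
cortical hypoperfusion; a subset of patients progress to vascular mild
cognitive impairment (vMCI). Structural diffusion MRI (DTI) summarizes
white-matter microstructure through atlas-wise means of FA, MD, AD and RD over
the 48 ICBM-DTI-81 labels; arterial spin labeling gives mean cerebral blood
flow (CBF) over the 116 AAL gray-matter labels. Together these yield a
subjects-by-308 feature table (192 diffusion + 116 perfusion features). The
package asks three questions of such a table:

1. Which features discriminate vMCI patients from cognitively normal SVD
   patients, when selection is honest (no subject influences the selection of
   the features used to classify it)?
2. How well does a sparse logistic classifier on those features perform, and
   does combining modalities beat either alone?
3. Are the discriminative features associated with attention-executive
   performance, after adjusting for sex, age and education?

## The procedure

**Nested 10x10 feature selection.** Subjects are split into 10 outer folds
stratified by (diagnosis, sex); within each outer-training set, 10 inner folds
are formed the same way. For each inner fold the 0/1 diagnosis label is
regressed on all features by the linear lasso; the penalty is chosen by
10-fold cross-validated mean squared error (minimum rule, ties toward the
sparser side; a 1-SE variant is available via `lasso_config(cv_rule)`). The
ten inner supports are combined by union, so a feature that matters on any
subsample survives. Each outer fold's members form a *testing pool*: all
leave-one-out iterations for subjects of a pool share that pool's reduced
feature set, which by construction was computed without any of them. The
`train` ids are stored with each pool so the no-leak property is
machine-checkable rather than merely asserted.

**Sparse logistic regression with LOOCV.** Each subject is predicted by an
L1-penalized logistic model (penalty on standardized feature weights, never on
the intercept) trained on the other n-1 subjects, restricted to the subject's
pool features. The vMCI probability is `1 / (1 + exp(-w'z))` with `z` the
standardized feature vector augmented by 1. The penalty is chosen once per
pool by 10-fold cross-validated deviance on the subjects outside the pool; we
default to the 1-SE rule, the standard choice when the fitted model is itself
the object of interest and sparsity is wanted (deviance-minimum is a config
option). Classification uses the fixed 0.5 threshold.

**Consensus discriminative features.** For each feature we report the fraction
of the n LOOCV fold-models in which it carried a nonzero weight; features at
or above the (inclusive) 0.75 threshold form the consensus set. Counting
nonzero *classifier weights* rather than reduced-set membership is deliberate:
membership frequencies can only be sums of pool-size fractions (multiples of
roughly 0.1), which cannot produce the fine-grained frequencies a per-model
count yields. Both semantics are implemented
(`consensus_features(semantics =)`).

**Evaluation.** Accuracy/sensitivity/specificity from the LOOCV confusion
matrix; ROC by threshold sweep with (0,0)/(1,1) anchors and trapezoidal AUC
(equal, to machine precision, to the tie-corrected concordance statistic);
paired classifiers are compared with McNemar's test on discordant
correct/incorrect classifications — continuity-corrected chi-square when
`b + c >= 25`, exact two-sided binomial otherwise. McNemar compares paired
classifications, not AUCs; a DeLong AUC test is a deliberate non-goal.

**Associations.** Partial Pearson correlations between consensus features and
cognitive scores (TMT-A, TMT-B, Stroop C-T, VFT), controlling sex (0/1
indicator), age and education, computed within a diagnostic group by
residualizing both variables on the covariates plus intercept;
`t = r sqrt(df / (1 - r^2))` with `df = n - 2 - 3`. Benjamini–Hochberg
correction is applied within each cognitive test across features, separately
per group — the family a per-test results column implies; a whole-table family
is a config option. Group comparisons elsewhere use a Lilliefors-corrected
Kolmogorov–Smirnov normality gate at alpha = 0.05 (both groups normal →
Welch t-test; otherwise Wilcoxon rank-sum with normal approximation and tie
correction); a plain KS test against a fully specified normal would be
anti-conservative with estimated parameters. Sex proportions are compared by
Pearson chi-square without continuity correction.

## The synthetic cohort generator

No clinical data ship with the package; `generate_cohort()` emulates the
structure the analysis assumes, and `default_paper_config()` pins the study
conditions: 74 vMCI cases and 39 controls; 13 planted discriminative features
with the published group means (8 CBF regions, 4 FA tracts, 1 AD tract, e.g.
right Rolandic operculum CBF 49.215 vs 55.617 mL/100g/min, right anterior
corona radiata FA 0.316 vs 0.346); and 7 planted within-case partial
correlations with the executive tests (e.g. right-ACR FA vs TMT-B,
r = -0.404).

Choices a user should know:

* **Effect scale.** The study reports group means but no SDs for the
  discriminative features, so planted SDs are set to give Cohen's d = 0.8 —
  strong but realistic for effects that survive FDR at n = 113 — via
  `sd = |mean difference| / d`; `d` is an argument.
* **Dependence.** Background noise is exchangeable within modality
  (correlation 0.3, one shared factor per modality), the simplest structure
  that exercises the lasso's correlated-predictor behaviour. Real feature
  tables have block/spatial covariance; nothing here emulates that, so
  passing tests say nothing about atlas-level spatial structure.
* **Cognitive scores** are linear in the covariates (timed tests worsen with
  age, improve with education) plus, within the case group, a linear
  combination of the planted features whose coefficients are solved
  analytically and jointly — `c = s D^{-1} R^{-1} r` with
  `s = sigma / sqrt(1 - r' R^{-1} r)` — so every planted (feature, test) pair
  has *exactly* its target partial correlation in population, even when
  several correlated features load on the same test. The within-case score SD
  therefore exceeds the nominal group SD by the planted-signal share; group
  mean separations follow the published demographic table.
* **Demographics.** Age ~ N(66.0, 6.8) cases / N(63.4, 7.0) controls,
  education ~ N(10.5, 2.6), truncated at plausible bounds; sex is ~77% male in
  both groups, so stratified folds exercise small female strata.

## Numerical choices

The lasso is solved by cyclic coordinate descent with internal
standardization per fit (1/n variance convention) and back-transformation to
the input scale; `lambda_max = max_j |<x_j, y>|/n` on the standardized scale.
Convergence follows the reference coordinate-descent convention — maximum
variance-weighted squared coefficient change below `tol` (default 1e-7);
path fits inside cross-validation use warm starts plus standard saturation
stopping (R^2 > 0.999, deviance-gain < 1e-5 per step, or active set larger
than n; later path points reuse the last solution). In the p > n regime the
saturated tail of the path is degenerate and never wins cross-validation, but
solving it to high precision would dominate the entire pipeline's cost.
Coefficients below 1e-12 after back-transformation are treated as exact
zeros. The logistic solver runs coordinate descent inside IRLS with weights
floored at 1e-5; the outer loop stops on the relative change of the penalized
objective, which is robust to the slow weight drift of quasi-separated p > n
fits; a diverged unpenalized fit (|linear predictor| > 25) raises the
perfect-separation error. One global seed fans out to stage seeds through a
multiplicative hash (`derive_seed`), and all fold randomness is keyed to
sorted subject ids, so file row order can never change a result.

Degenerate inputs: constant feature columns are dropped from selection (and
get exactly zero coefficients in fits); an empty reduced set predicts its pool
at the training base rate with a warning; an inner training portion with a
single class is an error naming the fold; missing values are rejected at
load, never imputed.

## What the tests do and do not show

The test suite runs the whole pipeline on generated cohorts at the default
study conditions (113 subjects, 308 features; 20 replicate seeds for the
recovery surface) and smaller cohorts elsewhere; the calibration checks use
500 null cohorts with 20 features for the per-feature test level and 200 for
the FDR family rate. These sizes are the package's chosen compromise between
Monte-Carlo error and a test suite that runs in minutes.

One property deserves honesty rather than a green tick: with a shared noise
factor per modality, non-planted features are genuinely informative in finite
samples (they proxy the factor that also perturbs the planted features), so
an L1 logistic model at any cross-validated penalty stably retains a few
dozen of them, and — because leave-one-out training sets differ by a single
subject — the same ones recur in nearly all folds. The consensus set
therefore recovers the planted features reliably (typically 11-12 of 13) but
also contains on the order of ten stable non-planted features at these
settings. Reading the consensus set as exactly the planted support is not
supported under correlated backgrounds; it is a stability ranking, not a
support estimator. The same behaviour is reproduced by the independent
reference lasso implementation, so it is a property of the method under these
conditions, not of this solver.

## Known limitations

* The feature-selection stage regresses a 0/1 label with a least-squares
  lasso, mirroring the emulated analysis; a logistic-loss selection stage is
  out of scope.
* The sparse classifier is L1-penalized logistic regression; an ARD/Bayesian
  sparse logistic variant is out of scope.
* No image-level processing: the pipeline starts at extracted ROI means.
* Diffusivity units are the caller's concern: features are treated as
  unitless reals (the packaged defaults put AD on the conventional 1e-4
  mm^2/s reporting scale).
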