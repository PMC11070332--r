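---
title: "Screening causes of death from the postmortem metabolome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening causes of death from the postmortem metabolome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codscreen)
```

## The screening problem

Autopsy rates are falling, and untargeted high-resolution mass
spectrometry of femoral blood — already collected for routine forensic
toxicology — carries a metabolic signature of the agonal period and the
cause of death (CoD). `codscreen` implements a complete, tested pipeline
that turns a chromatographic feature table (cases × peaks, with m/z and
retention time per peak) and case metadata into a multi-class CoD
screening model for five groups: acidosis, drug intoxication, hanging,
ischemic heart disease (IHD) and pneumonia.

The pipeline reproduces a fixed study design:

1. a stratified 3:1 split into training and test partitions;
2. retention-time filtering, probabilistic quotient normalization (PQN),
   `log10` transform and unit-variance (UV) scaling;
3. per-group PCA outlier exclusion (Hotelling's T² *and* DModX, both at
   α = 0.05);
4. per-group, per-covariate PLS screening of features confounded with
   age, sex, BMI, postmortem interval (PMI) or analytical run date;
5. multi-class OPLS-DA of the retained features, refined once by
   removing features with VIP < 1.0;
6. class prediction, per-class ROC curves, and specificity-optimized
   screening thresholds taken from the steepest ROC segment inside the
   region TPR > 0.3, FPR < 0.1;
7. validation of the frozen artifacts on the untouched test partition.

Because real forensic cohorts cannot be redistributed, the package
ships a synthetic cohort generator whose defaults emulate the study
conditions (group sizes, covariate distributions, batch structure,
dilution, confounding, outliers) with full ground-truth annotation, so
every stage can be tested against known planted signals.

## Models

### Preprocessing

PQN estimates a per-case dilution factor as the median of the
intensity quotients against a reference spectrum — the per-feature
median over the case set. Features with zero reference intensity are
excluded from the quotient; the normalized table is the input divided
by the factor. The reference is computed once on the training set and
reused for test cases, so no information flows backwards from the test
partition (`pqn_normalize(table, reference = ...)`). Whether dilution
correction precedes or follows retention-time filtering is immaterial
for the factors' ranks but we filter first, so the reference is built
only from features that will be modeled.

All modeling operates on `log10(x + x0)` with per-feature centering and
scaling to unit sample standard deviation (n − 1 throughout). The
pseudo-value `x0` is zero when the table has no zeros, otherwise half
the smallest positive intensity — a conventional choice that keeps the
transform monotone without inventing precision below the detection
limit. Zero-variance features cannot be scaled and are dropped with a
warning.

### Latent-variable core

PCA is computed by NIPALS (unit-norm loadings, orthogonal scores; the
suite verifies equality with the SVD to 10⁻⁸ on small matrices). For
an A-component model of N cases and K features the outlier diagnostics
are

* Hotelling's T² = Σₐ tₐ²/var(tₐ), with critical value
  A(N² − 1)/(N(N − A)) · F₀.₉₅(A, N − A) — a score-space (severe)
  deviation;
* DModX = sᵢ/s₀, where sᵢ² = Σₖ eᵢₖ²/(K − A) and s₀ is the pooled
  training residual standard deviation, with critical value
  √F₀.₉₅(K − A, N − A − 1) — a residual-space (moderate) deviation.

The DModX critical value is an F-approximation of the rule used by
commercial chemometrics software, whose exact formula is proprietary;
a calibration test asserts that the false-flag rate on clean Gaussian
data stays near the nominal α. A case is excluded as an outlier only
when *both* diagnostics exceed their critical values, and excluded
cases are only removed from model *fitting* — at prediction time they
are genuine cases a screening tool must handle, and they re-enter the
prediction counts.

PLS components are extracted by NIPALS; each X-weight is the exact
NIPALS fixed point, computed through the small G × G eigenproblem of
(YᵀX)(XᵀY) for determinism. Covariate models (one per CoD group and
covariate; PLS-DA with a two-column indicator for sex, ordinal day
number for run date) retain a component only while its incremental
seven-fold cross-validated Q² exceeds 0.01, capped at five components.
A covariate "produces a model" when at least one component survives —
this operationalizes, through cross-validation, whether a covariate can
explain metabolome variance in a group at all. A feature is excluded as
confounded when |p(corr)| — its Pearson correlation with the model's
first score — exceeds 0.5 in at least three groups *with* models; if
fewer than three groups produce a model, the covariate excludes
nothing. The 0.5 threshold is a config knob
(`pipeline_config(pcorr_threshold = ...)`); values an order of
magnitude lower would exclude essentially every feature and leave
nothing to model.

### Multi-class OPLS-DA

Class membership is one-hot coded and column-centered. Orthogonal
variation is removed iteratively: each orthogonal weight is the part of
the current leading predictive loading orthogonal to the span of XᵀY,
which makes the orthogonal scores *exactly* uncorrelated with every
class column. The predictive block is a NIPALS PLS2 regression of the
filtered matrix on the indicator matrix; because the indicator rows sum
to one, predicted responses sum to one algebraically, and the per-class
response acts as a soft membership score.

Both component counts are selected by the same seven-fold
cross-validation rule (accept while cumulative Q² improves by more than
0.01): predictive components starting from G − 1 (the minimum spanning
all class contrasts, capped at 12), then orthogonal components (capped
at 10). The predictive count is cross-validated rather than fixed at
G − 1 deliberately: with class shares as skewed as this design's
(roughly 2% to 32%), the first G − 1 covariance-maximizing components
are all spent refining the large-class contrasts, and the rare-class
contrast is only captured by later components; cross-validation detects
exactly when additional components stop paying for themselves. Folds
are stratified by class after a seeded shuffle, exhaustive and
disjoint. R² is the fraction of response sum-of-squares explained in
fit; Q² = 1 − PRESS/SS against the fold-training class means.

VIP over the predictive components,
VIPₖ = √(K · Σₐ SSYₐ wₐₖ² / Σₐ SSYₐ), has mean square one by
construction, so the refinement cut VIP ≥ 1.0 keeps features of
above-average influence and can never empty the feature set. VIP here
uses predictive components only; a variant including orthogonal
variation would dilute the class-relevance interpretation of the cut.

### Screening thresholds

Per-class one-vs-rest ROC curves are built from *cross-validated*
training responses: each fitting case is predicted by a model refitted
without its fold (same component structure), while outlier cases —
never part of any fit — keep their full-model predictions. Thresholds
chosen on fitted responses do not transfer: in-sample responses are
optimistically separated whenever the feature count is comparable to
the case count, and thresholds placed on them collapse test-set
sensitivity. Cross-validated responses estimate the response scale the
model actually produces for unseen cases.

Within the predetermined region (TPR > 0.3, FPR < 0.1, evaluated at a
segment's upper endpoint) the steepest ROC segment is selected; a
vertical segment (ΔFPR = 0) counts as infinitely steep. Ties prefer
lower FPR, then higher TPR, so a contiguous vertical rise is used in
full. The returned threshold realizes the segment's upper operating
point; both the threshold and its (TPR, FPR) are recorded. Screening
assigns a case to *every* class whose response reaches its threshold,
yielding `none` / `unique` / `multiple` outcomes; diagnostic metrics
(PPV, NPV, sensitivity, specificity, accuracy) are reported per class
as percentages rounded half-up to one decimal, with each case counted
once per one-vs-rest contrast.

For single-label evaluation the package uses the maximal predicted
response (ties broken by class order and flagged). A per-class
equal-error-rate mode (`equal_error_threshold()`, the threshold where
sensitivity balances specificity) is also exposed, since default class
prediction in commercial chemometrics software behaves this way; it is
not the default here because with five classes the argmax is the
transparent choice and the specificity-optimized thresholds cover the
screening use case.

## The synthetic cohort generator

`synthetic_config()` fixes the study conditions. Per group, covariates
are drawn to match the published cohort's summaries: age, BMI and PMI
from log-normal distributions with the target median and a log-sd
matched to the target interquartile range, sex as Bernoulli with the
target female share, run date uniform over 641 analytical runs. The
log-intensity of feature k in case i sums:

* a feature baseline (log peak area ~ N(11.5, 1));
* a group-discriminant shift for 30 planted features per group
  (default 0.5 natural-log units, random sign per feature), scaled per
  group by (largest group size / group size)^0.75 — the rare groups
  (acidosis, pneumonia) get proportionally more distinct fingerprints,
  mirroring the empirical pattern that they are the most metabolically
  distinct, and keeping each class detectable under one shared model
  despite class shares from 2% to 32%;
* a covariate term for 25 planted features per covariate (slope 2.0
  log units per covariate SD, random sign) — strong enough that the
  within-group |p(corr)| clears the 0.5 exclusion threshold;
* six latent "metabolic state" factors with dense N(0, 0.3²) loadings —
  the correlated inter-individual variation that dominates the leading
  principal components of real cohort data, without which per-group PCA
  would model pure noise;
* a per-run batch offset (log-sd 0.1) and a per-sample dilution
  (log-sd 0.3), which multiply every feature of a sample; their product
  is the recoverable "true dilution" recorded in the ground truth;
* i.i.d. measurement noise (log-sd 0.6).

Outlier cases (3%) combine a ±4 SD displacement of two latent scores
(an in-model-plane, severe deviation that drives T²) with a
multiplicative inflation of a random 15% of features by e² (an
off-plane, moderate deviation that drives DModX) — so the dual
exclusion rule, which requires both, can find them.

What the generator does *not* emulate: non-linear covariate effects,
correlated confounders, drift within an analytical run, missing values
and detection-limit censoring, heavy-tailed intensity noise, and any
real metabolite identities. Passing recovery tests on this cohort
therefore demonstrates that the pipeline's machinery is correct under
its own assumptions, not that real postmortem data meet those
assumptions.

## Problem sizes and numerical choices

The default generated cohort is 25% of the full study sizes
(1071 cases: 25/346/300/341/59 per group). At this scale every group
retains enough cases for stable per-group PCA diagnostics and
seven-fold cross-validation after the 3:1 split; full-size generation
(`scale = 1`) remains available. The test suite runs its structural
checks on still smaller purpose-built cohorts and reserves the default
cohort for the ground-truth recovery properties.

Numerical conventions worth knowing:

* sample (n − 1) standard deviations everywhere;
* half-up rounding for reported percentages (one decimal for metric
  tables, whole numbers for overall rates), matching how such tables
  are conventionally printed;
* deterministic signs for NIPALS components (largest-magnitude loading
  positive), so fits are reproducible to the bit;
* every source of randomness (generation, splits, fold shuffles) is
  seeded through a single integer per run; artifacts serialize to JSON
  with 17 significant digits, which round-trips doubles exactly;
* degenerate inputs fail loudly: empty tables, all-zero matrices,
  constant responses, single-class ROC inputs and feature-set
  mismatches are errors, not silent results.

## Known limitations

The DModX critical value and the "both diagnostics" exclusion rule are
approximations of proprietary software behavior, validated only by
calibration on Gaussian data. The confusion-matrix convention counts a
dual-assigned case once in each involved one-vs-rest contrast; printed
specificities under other conventions can differ by a tenth of a
percentage point. The generator's planted effects are additive in log
space and the balance exponent (0.75) is a design choice of this
package, not an estimate from data. Finally, reported Q² values on
near-separable synthetic cohorts are far higher than what real
postmortem cohorts yield; the synthetic defaults are tuned for testable
ground-truth recovery, not for mimicking real-data difficulty.
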