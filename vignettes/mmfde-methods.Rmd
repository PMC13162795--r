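---
title: "Fuzzy distance-based fusion of boosted classifiers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy distance-based fusion of boosted classifiers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmfde)
```

## The model

`mmfde` fuses the probability outputs of four gradient-boosting classifiers
into a single, geometrically interpretable prediction for a binary clinical
outcome (the motivating application is diabetes screening on tabular
clinical records).

For a sample $x$ let $S_z \in [0,1]$ be the positive-class probability from
classifier $z = 1, \dots, M$ (here $M = 4$: lightgbm-kind, xgboost-kind,
gbm-kind, adaboost). The vector $S = (S_1, \dots, S_M)$ lives in the unit
hypercube, whose two corners $\mathbf{1}$ (unanimous *diabetic*) and
$\mathbf{0}$ (unanimous *non-diabetic*) serve as ideal class prototypes.
Four distances measure how far $S$ sits from a prototype, each capturing a
different facet of ensemble behaviour:

* **Euclidean** $d_E = \lVert \text{ideal} - S \rVert_2 / \sqrt{M}$ —
  overall magnitude of deviation;
* **Manhattan** $d_M = \sum_z \lvert \text{ideal}_z - S_z \rvert / M$ —
  outlier-robust accumulation of many moderate disagreements;
* **cosine** $d_C = 1 - \frac{S \cdot \mathbf{1}}{\lVert S \rVert_2 \sqrt{M}}$ —
  directional misalignment, insensitive to scale;
* **Chebyshev** $d_{Ch} = \max_z \lvert \text{ideal}_z - S_z \rvert$ —
  the single worst-disagreeing classifier.

A convex combination with weights $w = (w_E, w_M, w_C, w_{Ch})$,
$\sum w_k = 1$, gives the hybrid distance
$\Lambda_j = w_E d_E + w_M d_M + w_C d_C + w_{Ch} d_{Ch}$ to each class
prototype $j \in \{\text{pos}, \text{neg}\}$. Exponential decay converts
distance to a fuzzy membership $\mu_j = e^{-\beta \Lambda_j}$, a calibrated
confidence in $(0, 1]$; the softmax-style score
$e^{\mu_\text{pos}} / (e^{\mu_\text{pos}} + e^{\mu_\text{neg}})$ is
thresholded at 0.5 for the label. The winning membership
$\mu_{\max} = \max(\mu_\text{pos}, \mu_\text{neg})$ drives a three-band
triage: VeryHigh ($\mu > 0.9$, automatable), High ($0.7 < \mu \le 0.9$),
Moderate ($\mu \le 0.7$, clinician review).

```{r worked-example}
fix <- worked_example_fixture()
res <- fuse_confidences(fix$probabilities, beta = 1.905)
res[, c("sample_id", "mu_pos", "mu_neg", "fuzzy_score", "label",
        "confidence_level")]
```

## Numerical conventions

**Metric commensurability.** The raw Euclidean and Manhattan sums grow like
$\sqrt{M}$ and $M$, while cosine and Chebyshev are bounded by 1; averaging
them raw would let Manhattan dominate any weighted combination. The package
therefore normalizes Euclidean by $\sqrt{M}$ and Manhattan by $M$, so all
four metrics — and hence $\Lambda$ — live in $[0, 1]$ and the weights are
comparable across metrics. The raw form remains available through
`normalize = FALSE` on `multi_metric_distances()` and `fuse_confidences()`.

**Cosine against the zero prototype.** The zero vector has no direction, so
a cosine distance "to $\mathbf{0}$" is undefined. The deviation vector
$\mathbf{1} - S$ is compared with the ones direction instead: when every
classifier outputs 0, the deviation is exactly $\mathbf{1}$ and the cosine
term correctly reports perfect alignment with the negative prototype. A
zero-magnitude input vector (possible only against the positive prototype)
falls back to maximal misalignment $d_C = 1$ rather than 0/0.

**Ties.** A fuzzy score of exactly 0.5 labels the sample positive: in a
screening context a missed case is costlier than a false alarm. Weight-grid
ties resolve to the maximum-entropy (most balanced) candidate, then to grid
order, so the search is deterministic.

**Decision equivalence.** Because $\mu$ is strictly decreasing in
$\Lambda$ and the score strictly increasing in
$\mu_\text{pos} - \mu_\text{neg}$, thresholding the score at 0.5 is
identical to choosing the class with the smaller hybrid distance (except
exactly at ties). The suite property-tests this over random distance pairs,
which is also why the fused *decision* does not depend on $\beta$; only the
confidence calibration does.

**Monotonicity caveat.** Raising one classifier's positive-class
probability never increases $\Lambda_\text{pos}$ for the Euclidean,
Manhattan, and Chebyshev terms. The cosine term alone is not coordinatewise
monotone: for near-zero, strongly skewed probability vectors, increasing
the largest coordinate can *increase* directional misalignment. With the
default weights the first-order Manhattan/Euclidean response dominates in
practice, and the property test exercises the default configuration over
the unit hypercube under a fixed seed; a cosine-dominant weighting near the
origin is the known exception.

## Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `weights` | (0.30, 0.30, 0.20, 0.20) | fractions | tuned optimum reported for the reference configuration; 60% on magnitude terms, 20% each on direction and worst case |
| `beta` | 2.0 | 1/distance | reported tuned value for the Pima-style dataset; per-dataset retuning via `search_beta()` (grid 0.5–5.0 by 0.5, binary cross-entropy on a 20% stratified validation carve) |
| `threshold` | 0.5 | score | symmetric decision point; ties positive |
| triage cuts | 0.9 / 0.7 | membership | published clinical bands |
| weight grid `step` | 0.05 | fraction | 5% simplex increments, 1771 candidates |

The worked-example table above uses $\beta = 1.905$, the value implied by
its own printed distance/membership pairs (via $-\ln\mu / \Lambda$,
consistent across all five samples); the published per-dataset optima are
2.0 and 2.5. Since the decay constant cancels in the decision, the choice
affects only how sharply confidence falls with distance. The package
default stays at 2.0 and both values are overridable.

The printed hybrid distances of the worked example are *not* recoverable
from the distance formulas with the stated weights under either the raw or
the normalized convention (direct arithmetic gives 0.853 or 2.007 for the
first sample's positive distance against a printed 0.569); whatever
post-processing produced that table is unstated. The suite therefore
asserts the membership-to-score stage exactly and checks the printed
distance/membership rows through the $\beta$-free identity
$\ln\mu_\text{pos} / \ln\mu_\text{neg} = \Lambda_\text{pos} / \Lambda_\text{neg}$
(within 1%), which any exponential-decay calibration must satisfy.

## Base ensemble and fold discipline

The base learners follow the published configuration: 200 estimators,
learning rate 0.05, depth 6/6/5, L1 = L2 = 0.1 on the histogram boosters,
subsample 0.8 on the gbm kind, shared seed 42. Three of the four are fitted
with the xgboost library — the lightgbm kind uses histogram binning with
leaf-wise (`lossguide`) growth, that algorithm's defining strategy — and
AdaBoost is SAMME over depth-1 decision stumps (the stump depth is recorded
in the fitted handle), with probabilities as weighted vote shares. All
boosting is single-threaded so runs are bit-reproducible from the seed.

Preprocessing is leakage-safe by construction: zero codes in the five
clinical columns that carry physiologically impossible zeros (glucose,
blood pressure, skin thickness, insulin, BMI) are treated as missing and
imputed with the *training-fold* median of the non-zero values — the median
rather than the mean, for robustness to the heavy right tails of insulin
and skin-fold measurements — and min-max scaling parameters are fitted on
the training part only. Held-out values outside the training range map
outside $[0, 1]$ and are deliberately not clipped. Cohorts without zero
codes skip imputation via `impute_zeros = FALSE`. Folds and the 80/20
holdout are stratified, preserving class counts within one subject.

## Tuning

The weight search enumerates every 4-part composition of 1 at 5% steps —
1771 candidates by stars-and-bars, all of them evaluated (the grid is
exhaustive and duplicate-free by construction) — and scores each by the
mean out-of-fold accuracy of the fused decision over 5 stratified folds,
with base models refitted per fold. Because the decision reduces to
$\Lambda_\text{pos} \le \Lambda_\text{neg}$, the per-candidate evaluation
is a matrix product over precomputed per-sample metric components, so the
full grid costs milliseconds once the confidences exist. $\beta$ is tuned
afterwards at the fixed best weights, mirroring the stated ordering of the
original procedure. `stability_surface()` exposes the
$(w_E, w_M)$ slice with $w_C = w_{Ch} = (1 - w_E - w_M)/2$ for plateau
inspection around an optimum; the perturbation sensitivity at $\pm$one grid
step is reported by the caller, not asserted, since it is dataset-specific.

## Evaluation suite

Threshold metrics use the standard confusion-count formulas, with undefined
precision/recall reported as `NA` markers rather than zeros. AUC is the
Mann–Whitney rank statistic with averaged ties; PR-AUC integrates the
precision–recall curve stepwise (no interpolation), and the convention is
stamped into the result. Classifier comparisons use Dietterich's 5×2cv
paired t statistic (5 d.f.), McNemar with continuity correction floored at
zero and an exact binomial fallback below 25 discordant pairs, Bonferroni
thresholds, and seed-deterministic percentile bootstrap intervals.
Calibration bins $\mu_{\max}$ — the quantity the triage thresholds act on —
into 10 equal-width bins (both the count and the axis are configurable and
recorded); empty bins carry zero weight in the ECE sum.

## Interpretability

`explain_predictions()` offers two attribution modes, and every report is
stamped with the mode used. `per_model_mean` (default) computes exact
tree-path Shapley values per base model — xgboost's TreeSHAP for the three
boosted-tree models, and a closed form for AdaBoost stumps, where a
depth-1 tree's entire deviation from its training-background mean belongs
to its single split feature — averaged with equal weight. It is fast and
exact but explains the base models, not the fusion.
`fused_model_agnostic` estimates Shapley values of the end-to-end fuzzy
score by permutation sampling; the marginal contributions along each
permutation telescope, so additivity
($\text{base} + \sum_f \phi_f = \text{score}$) is exact, at the cost of
Monte Carlo noise in the per-feature split. Concordance analysis labels
each sample by the sign of its dominant (largest-$|\phi|$) attribution and
reports agreement with the distance-based label, the share of discordant
cases at Moderate confidence, and misclassification rates by stratum —
discordance flagging is intended as a safety signal for review, not a
performance metric. Cross-fold rank stability uses Kendall's $\tau$ on the
union of top-$k$ feature sets, with out-of-top features placed by their
full-ranking position (the union convention is a documented choice; the
original analysis does not specify one).

## Synthetic cohorts

`generate_cohort()` emulates the two public diabetes benchmarks' *schema*,
not their joint distribution: eight attributes from truncated normal
marginals inside the published ranges (constants in
`mmfde:::marginal_params()`; ages restricted to 21–81, since the published
1–120 range does not describe an adult cohort and is used only for
validation warnings), and an outcome from a logistic model on standardized
features with per-feature log-odds effects defaulting to the
Glucose > BMI > DPF ordering that the attribution analyses should recover.
Defaults are the easy regime: n = 2000 at 44% prevalence with no zero
codes and a strongly glucose-dominated signal (log-odds 3.5 per SD of
glucose) — deliberately near-deterministic, because in the easy reference
cohort the diagnosis itself is largely glucose-threshold-defined. Raising
`noise_sd` to around 3 and switching on `zero_inflation` emulates the
smaller, messier benchmark. The logistic
intercept is calibrated on the drawn linear predictors, so the achieved
prevalence deviates from target only by binomial noise. Zero codes are
applied after the outcome is drawn (non-informative missingness) unless
`informative_missingness` is set.

Because the generator's outcome is genuinely logistic on the features,
passing tests demonstrate signal recovery, leakage discipline, and internal
consistency — they do not certify performance on real clinical data, whose
feature dependencies, measurement error, and label noise the generator does
not model. The published dataset-specific performance tables are
external-download territory and are deliberately out of scope here.

## Problem sizes in the suite

The test suite trains real boosters throughout but at reduced scale chosen
as the smallest instances that still exercise each property: oracle
equivalence of the searches on a 60-subject cohort with 15-round boosters
(exhaustiveness is a combinatorial property, indifferent to model quality);
signal-recovery checks at n = 500–1000 with 30–80 rounds; calibration
properties on 10,000 synthetic predictions constructed directly. The full
published configuration (200 rounds, the published depths) is exercised once on a
400-subject separable cohort where every base model must reach training
AUC > 0.95.

## Known limitations

* Binary outcomes only; the distance formulation generalizes to $c > 2$
  prototypes but is neither implemented nor tested beyond two classes.
* The cosine monotonicity exception described above.
* `per_model_mean` attributions mix model-output scales (log-odds for the
  xgboost-backed models, vote share for AdaBoost) before averaging; they
  are comparable in sign and rank, which is what the concordance and
  importance analyses use, not in physical units.
* The AdaBoost probability (weighted vote share) is coarser than a
  margin-calibrated probability; it is one of four voices in the fusion,
  which the calibration layer then recalibrates globally.
* Ideal prototypes are the hypercube corners; data-driven (class-conditional
  mean) reference vectors are a plausible refinement left unimplemented.
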