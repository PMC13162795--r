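# mmfde

Interpretable fusion of gradient-boosting classifiers for binary clinical
risk prediction, built around a multi-metric fuzzy distance geometry. The
motivating application is diabetes screening on tabular clinical records
(glucose, BMI, blood pressure, pedigree function, ...), for biostatisticians
and clinical-ML practitioners who need predictions a clinician can interrogate:
*how far is this patient from a prototypical case, how confident is the model,
and which features drove the call?*

## The method

Four base classifiers (lightgbm-kind, xgboost-kind, gbm-kind, AdaBoost)
produce positive-class probabilities `S = (S_1, ..., S_M)` per sample. `S`
is compared against the ideal diabetic prototype **1** and non-diabetic
prototype **0** under four complementary metrics — Euclidean
`‖ideal − S‖₂/√M` (overall deviation), Manhattan `Σ|ideal − S|/M`
(outlier-robust accumulation), cosine `1 − S·1/(‖S‖₂√M)` (directional
alignment), Chebyshev `max|ideal − S|` (worst-case disagreement) — combined
as a convex hybrid distance

    Λ_j = w_E d_E + w_M d_M + w_C d_C + w_Ch d_Ch,   j ∈ {pos, neg}

with weights tuned by exhaustive 5%-step simplex grid search (1771
candidates) under cross-validation. Exponential decay `μ_j = exp(−β Λ_j)`
turns distances into calibrated fuzzy memberships; the normalized score
`exp(μ_pos) / (exp(μ_pos) + exp(μ_neg))`, thresholded at 0.5, gives the
label, and `μ_max` drives a three-band clinical triage (VeryHigh > 0.9,
High 0.7–0.9, Moderate ≤ 0.7). Around the fusion core the package provides
the full study workflow: leakage-safe preprocessing (training-fold median
imputation of physiologically impossible zeros, min-max scaling),
stratified splits, weight/β tuning, a statistical comparison suite (5×2cv
paired t-test, McNemar, bootstrap CIs, Bonferroni), reliability/ECE
calibration analysis, SHAP-style attributions with geometric-vs-attribution
concordance, and a synthetic clinical cohort generator.

## Worked example

The five-sample demonstration embedded in the package (base-model
probabilities for five test subjects, one of them diabetic):

```r
library(mmfde)
fix <- worked_example_fixture()
fuse_confidences(fix$probabilities, beta = 1.905)
#> mmfde_fusion: 5 samples, beta=1.91, weights (E,M,C,Ch)=(0.30, 0.30, 0.20, 0.20)
#>   sample_id lambda_pos lambda_neg mu_pos mu_neg fuzzy_score label confidence_level
#> 1   sample1     0.8534    0.05694 0.1968 0.8972      0.3317     0             High
#> 2   sample2     0.7568    0.21427 0.2365 0.6649      0.3945     0         Moderate
#> 3   sample3     0.6393    0.23729 0.2959 0.6363      0.4157     0         Moderate
#> 4   sample4     0.6830    0.27384 0.2722 0.5935      0.4204     0         Moderate
#> 5   sample5     0.2851    0.56486 0.5810 0.3409      0.5597     1         Moderate
```

Sample 1 sits very close to the non-diabetic prototype (`lambda_neg` 0.057,
membership 0.90) and is labeled non-diabetic; sample 5 is the only one
closer to the diabetic prototype and is the single positive call — the
labels match the ground truth `fix$actual`. From the fixture's printed
membership pairs, the score stage reproduces the published values exactly:
`round(fuzzy_score(fix$mu_pos, fix$mu_neg), 4)` gives
`0.3429 0.3585 0.4670 0.3795 0.5967`.

A full synthetic run, generator → preprocess → train → fuse → evaluate →
explain:

```r
cohort <- generate_cohort(generator_spec(n = 1000, seed = 7))
sp  <- train_test_split(cohort, split_plan(seed = 7))      # stratified 80/20
pp  <- preprocess_cohort(cohort, fit_on = sp$train)        # leakage-safe
ens <- train_base_models(cohort_table(pp$features[sp$train, ],
                                      pp$outcome[sp$train], check_ranges = FALSE))
fused <- fuse_confidences(predict_confidences(ens, pp$features[sp$test, ]))
y <- cohort$outcome[sp$test]
classification_metrics(confusion_counts(fused$label, y))
#> metric_report (n=200): accuracy 0.8350, precision 0.8, recall 0.8276, f1 0.8136
ranking_metrics(fused$fuzzy_score, y)$auc
#> [1] 0.9170125
calibration_report(fused, y)
#> calibration_report: ECE 0.1071 (10 bins on mu_max)
#> triage distribution: Moderate 29.5%, High 60.5%, VeryHigh 10.0%
head(global_importance(explain_predictions(ens, pp$features[sp$test, ])), 3)
#>   feature importance
#> 1 Glucose  2.3066546
#> 2     BMI  0.8063381
#> 3     DPF  0.5112183
```

The attribution ranking recovers the generator's planted effect ordering
(Glucose > BMI > DPF); the ECE of 0.107 reflects the untuned default
`beta = 2` — tune per dataset with `search_beta()`. A thin CLI over the
same functions lives at `inst/cli/mmfde.R`
(`Rscript mmfde.R simulate|train|tune|fuse|evaluate|explain|report ...`);
every run writes a `manifest.json` from which its artifacts are
reproducible.

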