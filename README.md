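# codscreen

Cause-of-death (CoD) screening from postmortem metabolomics feature
tables.

Routine forensic toxicology already acquires untargeted high-resolution
LC-MS data from femoral blood at autopsy. The metabolic signature in
those data carries information about the chain of events at death, and
— at cohort scale — can screen cases into major CoD groups (acidosis,
drug intoxication, hanging, ischemic heart disease, pneumonia) before a
pathologist ever sees them. `codscreen` is an R implementation of that
screening analysis for forensic and clinical metabolomics researchers:
from a peak-intensity table and case metadata to per-group diagnostic
metrics, with every stage tested against planted ground truth.

## The method

Given a cases × features intensity matrix **X** and CoD labels coded as
a one-hot response **Y**, the pipeline:

1. filters features by retention time (90–660 s kept), corrects
   per-sample dilution by probabilistic quotient normalization
   (factor = median over features of x/ref, ref = per-feature median
   spectrum), and models `log10` intensities after unit-variance
   scaling;
2. excludes multivariate outlier cases per group when **both**
   Hotelling's T² (score distance) and DModX (residual distance) exceed
   their F-based critical values at α = 0.05 on a per-group NIPALS PCA;
3. excludes features confounded with age, sex, BMI, postmortem interval
   or analytical run date: per group and covariate, a cross-validated
   PLS model is fitted and a feature is dropped when |p(corr)| — its
   correlation with the first score — exceeds 0.5 in three or more
   groups that produced a model;
4. fits a multi-class OPLS-DA: orthogonal variation (uncorrelated with
   **Y** by construction) is split off, predictive components regress
   the filtered matrix on **Y**, and both component counts are chosen
   by 7-fold cross-validated Q²; the model is refined once by dropping
   features with VIP < 1.0 (VIP is normalized so mean VIP² = 1);
5. selects per-class screening thresholds at the steepest ROC segment
   within TPR > 0.3 and FPR < 0.1, computed from cross-validated
   training responses, and screens cases into `none` / `unique` /
   `multiple` outcomes with per-class PPV, NPV, sensitivity,
   specificity and accuracy.

A synthetic cohort generator (`synthetic_config()`, `generate_cohort()`)
emulates the five-group study population — covariate distributions,
batch structure, dilution, confounded and discriminant features, 3%
multivariate outliers — with ground-truth labels for every planted
signal, standing in for the ethically restricted forensic data.

## Worked example

```r
library(codscreen)

cohort <- generate_cohort(synthetic_config(seed = 42))
cohort
#> <synthetic_cohort> 1070 cases x 1321 features
#>          acidosis drug_intoxication           hanging               ihd         pneumonia
#>                25               346               300               340                59
#>   planted outliers: 32

split <- split_train_test(cohort, seed = 42)
artifacts <- run_training(split$train, pipeline_config(seed = 42))
artifacts
#> <cod_artifacts> 5 classes, 1205 features after screening, 287 at VIP cut
#>   final model: R2 = 0.888, Q2 = 0.867; training overall TP rate = 100%

validation <- run_validation(split$test, artifacts)
validation
#> <validation_report> overall TP rate = 100%
#>   AUC (test): acidosis 1.00, drug_intoxication 1.00, hanging 1.00, ihd 1.00, pneumonia 1.00
#>   screening: none 1%, unique 99%, multiple 0%
```

Of the 1,321 simulated features, 116 planted confounders are removed at
the screening stage (1,205 remain), VIP refinement keeps 287, and the
frozen model transfers to the untouched test partition with no loss of
AUC. Per-class screening metrics on the test partition:

```r
validation$screen$metrics[, c("group", "tp", "fp", "fn", "tn",
                              "sensitivity", "specificity", "accuracy")]
#>               group tp fp fn  tn sensitivity specificity accuracy
#> 1          acidosis  6  0  0 261       100.0       100.0    100.0
#> 2 drug_intoxication 86  2  0 179       100.0        98.9     99.3
#> 3           hanging 73  0  2 192        97.3       100.0     99.3
#> 4               ihd 84  0  1 182        98.8       100.0     99.6
#> 5         pneumonia 15  0  0 252       100.0       100.0    100.0
```

(The synthetic defaults plant a cleanly separable signal; real cohorts
are far harder — see the vignette's limitations section.)

The table-arithmetic utilities work directly on printed confusion
counts. For a screening group of 25 cases among 1,070 with counts
TP = 16, FP = 5, FN = 9, TN = 1040:

```r
confusion_metrics(16, 5, 9, 1040)
#>   tp fp fn   tn  ppv  npv sensitivity specificity accuracy
#> 1 16  5  9 1040 76.2 99.1          64        99.5     98.7
```

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic cohorts | `synthetic_config`, `generate_cohort`, `write_fixture`/`read_fixture` |
| Preprocessing | `filter_retention_time`, `pqn_normalize`, `log_uv_transform`, `qc_cv` |
| Latent models | `fit_pca`, `hotelling_t2`, `dmodx`, `fit_pls`, `p_corr`, `fit_oplsda`, `vip`, `predict_responses` |
| Screening workflow | `detect_group_outliers`, `screen_confounders`, `vip_refine` |
| Classification | `classify_argmax`, `roc_curve`, `steepest_threshold`, `threshold_screen`, `confusion_metrics`, `overall_rates`, `fp_contributing_review` |
| Downstream statistics | `characteristics_tests`, `anova_features`, `cluster_groups`, `match_mz` |
| Pipeline | `split_train_test`, `run_training`, `run_validation`, `save_artifacts`/`load_artifacts`, `pipeline_config` |
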