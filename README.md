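# eegleak

Band-energy EEG classification with leakage-aware cross-validation.

## The problem

Epoch-based EEG classification pipelines cut each subject's recording
into short overlapping windows, compute per-epoch features, and pool all
epochs into one table. Evaluating that table with ordinary k-fold
cross-validation places different epochs of the *same subject* in both
the training and the test split. Because resting EEG spectra are stable
within a person — every subject has a spectral fingerprint — the
classifier can recognise the individual instead of the diagnosis, and
k-fold accuracy is inflated, sometimes drastically. The subject-safe
alternative is leave-one-patient-out (LOPO) validation: all epochs of
one held-out subject per class form the test set, so train and test
subject sets are always disjoint.

`eegleak` implements the full pipeline for dementia-style EEG cohorts
(Alzheimer's disease AD, frontotemporal dementia FTD, healthy controls
CN) and both validation schemes, and ships a synthetic cohort generator
whose class-level spectral effects and subject-level fingerprints are
independently controllable — so the leakage inflation can be
demonstrated and quantified without any clinical data.

## The method

Per recording: artifact-interval removal → decimation 500 → 250 Hz
(zero-phase anti-alias low-pass) → zero-phase order-4 Butterworth
band-pass 0.5–48 Hz → 5 s epochs every 2.5 s. Per epoch and channel,
8 features:

* energies E_b = Σ x_f[n]² of the band-filtered signal in the five
  rhythm bands (delta 0.5–4, theta 4–8, alpha 8–12, beta 12–25,
  gamma 25–48 Hz),
* mean, population variance, and interquartile range.

For a 17-channel bipolar montage the table has 8 × 17 + 1 = 137 columns
(subject identity is row metadata, never a predictor). Six classifiers
(decision tree, random forest, MLP, linear SVM, naive Bayes, 1-NN) are
evaluated under pooled stratified 10-fold CV over epochs and under LOPO,
reporting accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
specificity = TN/(TN+FP) with patient class positive, and mean ± SD
(population, divisor N) across folds/iterations.

## Worked example: leakage on a class-null cohort

Generate a cohort with *no class signal at all* (`class_effect_scale = 0`)
but strong subject fingerprints, and compare the two schemes:

```r
library(eegleak)

spec <- cohort_spec(n_per_class = c(AD = 6, CN = 6), duration_s = 300,
                    sigma_subject = 1.0, class_effect_scale = 0, seed = 1)
ft <- cohort_features(generate_cohort(spec))
dim(ft)
#> [1] 1428  137

clf <- classifier_spec("knn")
pooled_kfold_cv(ft, clf, k = 10, seed = 2)
#> <cv_summary> kfold / knn: accuracy 0.999 (SD 0.002), sensitivity 0.999,
#>   specificity 1.000 over 10 iteration(s)
lopo_cv(ft, clf = clf, seed = 2)
#> <cv_summary> lopo / knn: accuracy 0.410 (SD 0.082), sensitivity 0.714,
#>   specificity 0.106 over 6 iteration(s)
```

The labels carry no information — yet pooled 10-fold reports ~100%
accuracy, because each test epoch has same-subject neighbours in the
training split. LOPO, which never lets a subject straddle the split,
stays at chance. The gap (here ~59 percentage points for 1-NN, ~29 for a
decision tree, ~17 for a random forest in the run recorded below) *is*
the leakage. With a genuine class effect (`class_effect_scale = 1`) both
schemes rise, but k-fold remains optimistic for every classifier.

The same experiment end-to-end, for all classifiers, schemes and
pairwise problems:

```r
cfg <- experiment_config(cohort = spec)
report <- run_experiment(cfg, verbose = TRUE)
report[, c("problem", "classifier", "kfold_accuracy", "lopo_accuracy",
           "gap_accuracy")]
```

A command-line front end with verbs `simulate`, `features`, `validate`,
`compare` and `sweep` is installed at `inst/cli/eegleak`; cohorts are
written as one EDF file per subject plus a CSV sidecar, features as CSV
with a parallel subject-grouping file.

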