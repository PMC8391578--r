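---
title: "Band-energy EEG classification and the epoch-leakage problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-energy EEG classification and the epoch-leakage problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegleak)
```

## The problem this package addresses

Clinical EEG classification studies commonly cut continuous multichannel
recordings into short, overlapping epochs, compute per-epoch spectral and
statistical features, and train a classifier on the pooled epoch table.
When such a table is evaluated with ordinary k-fold cross-validation over
epochs, different epochs of the *same person* routinely end up on both
sides of a split. Resting EEG spectra are highly stable within a person
over minutes — each subject has a spectral "fingerprint" — so the
classifier can score a test epoch by recognising the individual rather
than the diagnostic class. Pooled k-fold accuracy then measures subject
re-identification, not disease discrimination.

The subject-safe alternative holds out the *complete* epoch set of one
subject per class at each iteration (leave-one-patient-out, LOPO). The gap
between pooled k-fold accuracy and LOPO accuracy quantifies the leakage
optimism. `eegleak` implements both schemes around one feature pipeline
and ships a synthetic cohort generator in which class-level spectral
effects and subject-level fingerprints are *independently* controllable,
so the inflation can be demonstrated exactly: set the class effect to
zero, keep fingerprints strong, and any k-fold accuracy above chance is
leakage by construction.

## The pipeline

1. **Artifact removal** — artifact intervals (supplied as metadata; the
   package does not detect artifacts) are excised and the remaining
   maximal clean segments kept separately, so no epoch ever spans a cut.
2. **Decimation** 500 Hz → 250 Hz with a zero-phase order-4 Butterworth
   anti-alias low-pass at 0.8 × the new Nyquist before keeping every
   second sample. The subsequent conditioning band reaches 48 Hz, close
   to the 125 Hz Nyquist relative to the filter's roll-off, so explicit
   anti-aliasing is required.
3. **Conditioning band-pass** 0.5–48 Hz, order-4 Butterworth applied
   forward–backward (zero phase; effective magnitude response is the
   squared single-pass response). The upper corner also provides partial
   suppression of 50 Hz line interference. Note that a 4th-order
   Butterworth with its −3 dB corner at 48 Hz leaves a substantial
   fraction of a 50 Hz tone (zero-phase power ratio ≈ 0.39); the tests
   therefore assert agreement with the *designed* response rather than a
   fictitious rejection level.
4. **Epoching** — 5 s windows every 2.5 s (50% overlap) by default; the
   grid restarts in each clean segment; a trailing partial window is
   discarded. Counts follow `floor((T - dur)/stride) + 1`.
5. **Features** — per channel and epoch: energies (sum of squared
   samples after an order-4 zero-phase Butterworth band filter) in the
   five rhythm bands delta 0.5–4, theta 4–8, alpha 8–12, beta 12–25,
   gamma 25–48 Hz, plus mean, *population* variance (divisor N) and
   interquartile range of the conditioned signal. For a 17-channel
   montage this gives 8 × 17 = 136 predictors plus the class label — 137
   columns. Energies are absolute (no per-epoch normalisation). Subject
   identity is carried as row metadata and is never a predictor.
6. **Classification** — six classical learners (decision tree, random
   forest, MLP, linear SVM, Gaussian naive Bayes, k-NN) on every pairwise
   problem present (AD/CN, FTD/CN, AD/FTD), with the patient class as the
   positive class. Accuracy, sensitivity `TP/(TP+FN)` and specificity
   `TN/(TN+FP)` per fold; means and population SDs (divisor N) across
   folds.

```{r}
cfg <- experiment_config(
  cohort = cohort_spec(n_per_class = c(AD = 4, CN = 4), duration_s = 120,
                       sigma_subject = 0.5, class_effect_scale = 0,
                       seed = 1))
report <- run_experiment(cfg, verbose = TRUE)
report[, c("problem", "classifier", "kfold_accuracy", "lopo_accuracy",
           "gap_accuracy")]
```

## The generative model

Each subject carries a vector of log band powers

> subject log power = grand-mean profile
> + `class_effect_scale` × (class profile − grand-mean profile)
> + Normal(0, `sigma_subject`²) per band,

plus a log-normal per-channel gain (`sigma_gain`, default 0.1). A channel
is synthesised as a sum over bands of unit-variance Gaussian noise
confined to the band, weighted by the square root of the band power, plus
a small broadband noise floor (`noise_floor`, default 0.02, Butterworth
0.5–48 Hz). All randomness derives from one integer seed; identical
`(spec, seed)` reproduce cohorts bit for bit.

The default class profiles encode EEG slowing — relative shares
(delta, theta, alpha, beta, gamma):

* CN: 0.25, 0.15, 0.35, 0.18, 0.07 (posterior-dominant alpha),
* AD: 0.40, 0.25, 0.18, 0.12, 0.05 (marked slowing),
* FTD: 0.35, 0.22, 0.22, 0.14, 0.07 (intermediate).

Direction (delta/theta up, alpha/beta down in the patient groups) is the
modelled phenomenon; the magnitudes are plausible defaults and fully
configurable. `class_effect_scale = 0` collapses all classes onto the
grand-mean profile — the *null cohort* in which any above-chance pooled
k-fold accuracy is pure leakage. The default cohort shape mirrors the
clinical setting the package emulates: 10 AD, 10 FTD and 8 CN subjects,
13 min recordings for the patient groups and 21 min for controls, 500 Hz
native sampling on a 17-channel bipolar anterior–posterior montage. (The
published double-banana montage has 16 or 18 derivations depending on
whether the midline chain is included; the default list uses the four
lateral chains plus a single midline derivation to reach the 17 channels
of the emulated study, and the channel list is opaque configuration.)

### Why band components are synthesised *inside* their bands

The band-energy features are measured with order-4 Butterworth filters
whose −3 dB corners sit exactly on the band boundaries. Under zero-phase
(forward–backward) filtering the effective power response at a seam is
0.5² = 0.25, so two adjacent filters jointly recover only half of the
energy located exactly at their shared edge, and each filter's skirt
captures a few percent of a large neighbouring band. If the generator
parked band power right up against the seams (e.g. by shaping components
with the same Butterworth filters), these seam losses and skirt captures
would bias recovered band shares by 10–13% — a small band flanked by two
large ones (theta between delta and alpha) is hit hardest. We verified
this both by simulation and with an analytic capture-matrix model
(response-weighted spectral integrals over the full preprocessing chain).

The generator therefore synthesises each band component as FFT-masked
white noise confined to the nominal band inset by `band_margin` (default
0.15 of the band width) at each edge, capped at `max_component_hz`
(default 42 Hz). The inset keeps component power away from the seam
ambiguity; the cap keeps the synthetic gamma rhythm in the ~27–42 Hz
range — consistent with the 30–45 Hz band usually reported for scalp
gamma — and clear of both the conditioning filter's 48 Hz corner and the
50 Hz line-noise region, where the conditioning filter would otherwise
swallow a large share of it. With these defaults the worst-case
systematic error recovering the class profiles through the full pipeline
is about 8%, within the ±10% recovery tolerance the test suite asserts.
Under random subject fingerprints an adversarial profile (a small band
between two large neighbours) can still push single-channel recovery
error to ~11%; recovery is therefore asserted against the class profiles,
with shares averaged across channels.

## Validation schemes

**Pooled stratified k-fold** (`pooled_kfold_cv`): epochs are shuffled with
a fixed seed and dealt into k = 10 folds stratified by class, *ignoring
subject identity on purpose* — this is the leakage-prone procedure whose
optimism the package quantifies.

**Leave-one-subject-per-class-out** (`lopo_cv`): iterations equal the
larger class's subject count; subjects are taken in sorted order and the
smaller class is reused round-robin, so every subject is held out at
least once and train/test subject sets are disjoint at every iteration.
With unequal class sizes (10 patients vs 8 controls in the default
cohort) there is no canonical pairing of held-out subjects; round-robin
reuse of the smaller class is our resolution (an all-ordered-pairs
scheme would multiply runtime without changing the conclusion).

Chance-level checks on the null cohort use a binomial standard error at
the *held-out-subject* level, not the epoch level: predictions for epochs
of one held-out subject are strongly correlated (the classifier
effectively makes one decision per subject), so the exchangeable unit is
the subject slot. With 6 subjects per class this gives 12 slots and a
3 SE band of about ±0.43 around 0.5 — wide, but honest for a cohort of
this size.

## Classifier settings

* **Decision tree** — `rpart` with information-gain (entropy) splits and
  cost-complexity pruning (`cp = 0.01`), the closest available analogue
  of a C4.5-style tree with reduced-error pruning.
* **Random forest** — `randomForest`, 100 trees, `mtry = floor(sqrt(p))`.
* **MLP** — `nnet`, one hidden layer. The classic "(inputs + classes)/2"
  heuristic would give ~69 units and ~9.5k weights here; `nnet`'s BFGS
  optimiser keeps an O(weights²) working matrix, which is prohibitively
  slow and memory-hungry at that size, so the default is 10 units with
  weight decay 0.1 and 200 iterations, seeded.
* **SVM** — `e1071::svm`, linear kernel, C = 1.
* **Naive Bayes** — Gaussian, `e1071::naiveBayes`.
* **k-NN** — `class::knn` with k = 1 (the era-typical IBk default),
  exposed as a flag.

Features are standardised with training-fold statistics only, and only
for the scale-sensitive learners (MLP, SVM, k-NN); trees, forests and
naive Bayes consume raw features. Fitting a scaler on the full table
before splitting would be a second, subtler leakage channel.

## Numerical choices

* Zero-phase filtering uses odd-reflection padding of 3 × (filter length
  − 1) samples. Longer (whole-epoch) reflection padding was tried and
  *rejected*: for the narrow delta band the reflected extension
  correlates with the epoch content and inflates delta energy by ~15–20%.
* The five band filters approximately partition 0.5–48 Hz: for broadband
  noise the summed band energies fall within ~10% of the conditioned
  signal's energy (the deficit is the seam effect described above); the
  suite asserts 15%.
* Band edges at or above Nyquist, non-integer decimation factors,
  segments shorter than one epoch, single-class training splits and
  all-zero confusion tables are rejected or reported explicitly
  (undefined sensitivity/specificity become `NA`, never silent zeros).
* EDF output quantises to 16 bits over a symmetric per-channel physical
  range; round-trip error is below `max|x| / 32767` per channel, and
  features computed from an EDF round trip match in-memory features to
  well under 1%.
* Whether band energies should be epoch-normalised is left configurable
  in spirit: the features are absolute energies (the emulated pipeline
  does not mention normalisation), and relative shares are computed
  downstream where needed.

## Problem sizes used by the test suite

The acceptance-style tests run, per the package's own choice of cohort
sizes: the leakage demonstration on a null cohort of 6 + 6 subjects with
5-minute recordings (≈ 1 400 epochs × 137 columns), and the
scheme-ordering sweep on 4 + 4 subjects × 2 minutes at class-effect
scales 0, 0.5 and 1 for all six classifiers. Profile recovery and the
spectral-correctness checks use one-minute single-subject recordings.

## What the synthetic cohorts do *not* model

No 1/f spectral slope beyond the broadband floor, no eye-blink/EMG
artifact waveforms (artifact intervals are metadata, not simulated
physiology), no non-stationarity within a recording, no volume-conduction
correlation structure between channels (channels are independent
realisations sharing a subject's spectral profile), and no line noise.
Passing tests on these cohorts demonstrate the *validation-scheme*
mechanics — leakage inflation and its remedy — not clinical-grade
classification performance; the clinical accuracies of the emulated study
are not reproducible without its (undeposited) recordings.
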