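---
title: "Methods: early fusion of accelerometer, ECG and PPG for activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early fusion of accelerometer, ECG and PPG for activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wrist-worn inertial sensors are the workhorse of human activity
recognition (HAR), but some activity pairs — walking versus climbing
stairs above all — produce nearly identical arm-motion patterns and are
chronically confused by accelerometer-only classifiers. Cardiac signals
carry complementary information: stair climbing is markedly more
demanding than level walking, so the two activities that look alike to an
accelerometer differ strongly in heart rate. `fusionhar` implements a
feature-level ("early") fusion pipeline that quantifies how much a chest
ECG and a wrist PPG add to a wrist triaxial accelerometer (3D-ACC) when
recognising five daily activities: sitting, stairs, table soccer, cycling
and walking.

## Pipeline

The stages, each an exported function:

1. **Up-sampling** (`upsample_by_pairwise_average`, `upsample_record`).
   The 32 Hz accelerometer is raised to the PPG's 64 Hz by interleaving
   each consecutive pair of samples with its average. Down-sampling the
   PPG would discard half of it; the ECG stays at its native 700 Hz. The
   pairwise rule defines one value per gap; doubling the length needs one
   extra final value, and the implementation repeats the last sample —
   the simplest rule that preserves the signal's range.
2. **Windowing** (`extract_windows`). Non-overlapping windows of fixed
   duration (default 7 s) are cut *per labeled activity interval*,
   restarting at each boundary: every window is label-pure by
   construction and no voting rule is needed. A window of `w` seconds
   holds `round(w * rate)` samples per channel — 448 at 64 Hz, 4900 at
   700 Hz for 7 s. Overlapping windows are deliberately unsupported:
   neighbouring windows are not i.i.d., and overlap inflates apparent
   performance through train/test twins.
3. **Features** (`time_domain_features`, `amplitude_spectrum`,
   `frequency_domain_features`, `build_feature_matrix`). Seven
   time-domain statistics (mean, min, max, median, population SD,
   zero-crossing and mean-crossing counts) and eight frequency-domain
   ones per channel and window — 75 columns named
   `{signal}.{time|freq}.{feature}`. The spectrum is the one-sided
   amplitude spectrum of the raw (un-detrended, un-tapered) window,
   normalised so the DC bin equals the window's time-domain mean; gravity
   therefore makes DC the dominant accelerometer bin. For accelerometer
   spectra the peak feature is consequently the *second* maximum (largest
   non-DC bin, falling back to the overall runner-up if DC is ever not
   the maximum) and the dominant frequency is its frequency; cardiac
   signals are dynamic, DC does not dominate, and the global maximum is
   used. Crossing features are counts, not rates: at fixed window length
   the two differ by a constant factor, which no downstream model sees.
   Spectral summary statistics include the DC bin. All peak/tie decisions
   resolve toward the lowest frequency for determinism.
4. **Standardization** (`fit_standardizer`, `apply_standardizer`).
   Per-column z-scoring `z = (f − μ)/σ` with *population* σ. μ and σ are
   always fitted on the training partition alone and applied unchanged
   to the test partition; constant training columns map to zero.
5. **Selection** (`correlation_select`). Pairs of features with absolute
   pairwise Spearman rank correlation above 0.85 are redundant; the
   member less rank-correlated with the integer-coded activity labels
   (alphabetical label map) is dropped. Qualifying pairs are processed
   from highest |ρ| down (ties: lexicographic names; relevance ties drop
   the later name), skipping pairs already resolved — a deterministic
   greedy order that removes the worst redundancies first. Selection is
   refitted on every training partition (per subject, per LOSO fold)
   rather than once globally, which would leak test rows.
6. **Scenarios and models** (`scenario_columns`, `train_model`). Seven
   signal subsets — ACC, ECG, PPG alone; the three pairs; all three —
   index which feature columns reach the classifier. The headline model
   is a 300-tree random forest with depth cap 25 (the depth cap guards
   against over-fitting); k-nearest neighbours (k = 5) and
   ridge-penalised multinomial logistic regression sit behind the same
   interface for model comparison only. Remaining forest hyperparameters
   are `ranger` defaults, recorded by the package version.
7. **Evaluation** (`subject_specific_eval`, `loso_eval`,
   `weighted_scores`, `window_size_sweep`). Subject-specific ("personal")
   models use a stratified 80/20 split per subject with stratified
   10-fold CV on the training 80% (folds degrade to the smallest class
   count, with a warning); both the CV means and the held-out-20% scores
   are reported, since the protocol is run precisely to expose
   over-fitting gaps. Cross-subject models use leave-one-subject-out
   (LOSO): all preprocessing statistics and the model are refitted on the
   remaining subjects for every fold. Metrics are support-weighted F1 and
   support-weighted one-vs-rest AUC, plus per-activity F1 and the full
   confusion matrix (true labels as rows); cohort summaries are simple
   means over subjects. Whether a published subject-specific number is a
   CV mean or a test-set score is often ambiguous — this package reports
   both, labeled.

## The synthetic cohort

No external recordings ship with the package; `simulate_cohort` generates
them. Per activity the generator draws

* **accelerometer**: a constant 1 g gravity vector (fixed per posture
  group, jittered per subject so cross-subject orientation varies) plus
  sinusoids at the activity's motion fundamental and first harmonic,
  a slow shared amplitude envelope (15%, 5 s knots), and Gaussian noise;
* **ECG**: Gaussian-shaped R-peak pulses (σ = 20 ms) whose RR intervals
  follow the activity heart rate with per-beat jitter and a slow drift
  (SD 6 bpm, 10 s knots);
* **PPG**: a smooth raised-cosine pulse wave locked to the same beats,
  plus baseline wander, wideband noise and a motion artifact proportional
  to the instantaneous acceleration magnitude.

Per subject, a heart-rate offset (N(0, 6) bpm), a motion-amplitude scale
(U(0.8, 1.2)) and a fitness factor (U(0.85, 1.25), dividing the
heart-rate rise above a 60 bpm rest) are drawn from the master seed.
Field studies report fitness scores without much spread; the generator
exposes the factor without claiming to match any particular distribution.

The default profiles encode the study's qualitative premises as designed,
testable structure: walking (1.9 Hz) and stairs (1.8 Hz) share posture,
near-equal amplitudes and overlapping spectra but differ by 30 bpm;
sitting has the lowest heart rate and near-zero motion; heart rate climbs
with exertion (62, 85, 95, 115, 125 bpm for sitting, table soccer,
walking, cycling, stairs); PPG is the noisiest channel. Default protocol:
each activity for 120 s — a desk-scale session; `imbalanced_protocol`
reproduces daily-life class imbalance (walking 27%, sitting 24%, table
soccer 13%) instead. These values were fixed at design time as the
package's study conditions and are configurable but not tuned per run.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: true ECG morphology (P/T waves),
physiological PPG waveshape, non-stationary activity transitions,
sensor drift and dropout, and real between-subject gait diversity. The
pipeline's quantitative scores on this cohort characterise the pipeline
under controlled structure, not any real dataset; only the *qualitative*
contrasts (fusion benefit on the walking/stairs pair, signal ordering,
personal-vs-impersonal gap) are designed to transfer.

## Numerical and design choices

* Doubles are serialised with 17 significant digits; round-trips are
  bit-exact, and fixed-seed end-to-end runs are byte-identical.
* Spearman uses average ranks; correlations of constant columns are
  treated as 0 (never selected against, zero relevance).
* Tie-breaks everywhere are deterministic (lowest frequency, first class,
  lexicographic names).
* Windows shorter than 2 samples on any channel, empty protocols,
  unknown activities, overlapping label intervals, missing channels and
  single-class training sets all fail fast with named errors.
* Feature tables enumerate 7 + 8 features per channel, i.e. 75 columns
  over five channels; reports of a 77-feature total in this literature do
  not itemise the extra two, and this package commits to the enumerable
  75.
* Per-subject / per-fold seeds derive from one master seed
  (`derive_seeds`), so every protocol is a pure function of
  (config, seed).

## Problem sizes

The shipped tests exercise the pipeline on 4-subject, 60 s-per-activity
cohorts for unit checks and on 10-subject, 120 s-per-activity cohorts
across five master seeds for the qualitative-recovery checks; the
acceptance script uses one 10-subject cohort (850 windows, 75 features).
These sizes are the package's chosen study conditions for desk-scale
reproducibility; all of them are configurable upward.

## Known limitations

* The correlation-selection relevance score rank-correlates features with
  an integer-coded class label; for unordered activities this is a crude
  (if conventional) surrogate, kept for fidelity to the method family.
* Weighted one-vs-rest AUC is one of several multiclass AUC conventions;
  a class absent from a test partition is excluded from the weighted mean
  with a warning.
* Late (decision-level) fusion, deep sequence models, chest accelerometer
  channels and further bio-channels (respiration, EDA, temperature) are
  out of scope.
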