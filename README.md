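# fusionhar

Early fusion of wearable sensor signals for human activity recognition
(HAR): how much do cardiac signals — a chest ECG and a wrist PPG — add to
a wrist triaxial accelerometer (3D-ACC) when classifying five daily
activities (sitting, stairs, table soccer, cycling, walking)?

Accelerometer-only classifiers chronically confuse *walking* with
*climbing stairs*: the arm motion is nearly identical. The two activities
differ sharply in physical demand, hence in heart rate — so a classifier
fed both motion and cardiac features should resolve exactly that pair.
`fusionhar` implements the full feature-level ("early") fusion pipeline
needed to quantify this:

* **Preprocessing** — the 32 Hz accelerometer is up-sampled to the PPG's
  64 Hz by pairwise averaging (`x'_{2i} = x_i`,
  `x'_{2i+1} = (x_i + x_{i+1})/2`); the 700 Hz ECG is untouched. Signals
  are cut into non-overlapping, label-pure windows (default 7 s).
* **Features** — per channel and window, 7 time-domain statistics and 8
  frequency-domain features from the one-sided amplitude spectrum
  (normalised so the DC bin equals the window mean; accelerometer spectra
  use a *second-max* peak convention because gravity makes DC dominate):
  75 named columns `{signal}.{time|freq}.{feature}`.
* **Standardization & selection** — per-column z-scoring
  `z_i = (f_i − μ)/σ` with train-only μ, σ; then correlation-based
  feature selection: of every feature pair with |Spearman ρ| > 0.85, the
  member less rank-correlated with the activity labels is dropped.
* **Models & scenarios** — a 300-tree random forest (depth ≤ 25; KNN and
  multinomial logistic available for comparison) over seven signal
  scenarios: ACC / ECG / PPG alone, the three pairs, and all three.
* **Evaluation** — subject-specific models (stratified 80/20 split +
  stratified 10-fold CV on the training portion) and cross-subject
  leave-one-subject-out (LOSO) models; support-weighted F1 and
  one-vs-rest AUC, per-activity F1, confusion matrices, window-size
  sweeps, and mean-decrease-in-impurity feature-importance rankings.
* **Synthetic cohort** — a seeded generator
  (`simulate_cohort`) producing multi-rate ACC/PPG/ECG recordings with
  the qualitative structure above (motion-confusable but
  cardiac-separable walking/stairs, exertion-ordered heart rates, PPG
  motion artifacts), so everything runs offline and deterministically.

## Worked example

```r
library(fusionhar)

cohort   <- simulate_cohort(10, default_protocol(120), seed = 1)
features <- cohort_features(cohort, window_seconds = 7)   # 850 x 78

acc      <- loso_eval(features, scenario_id = 1, seed = 1)  # ACC only
acc_ecg  <- loso_eval(features, scenario_id = 4, seed = 1)  # ACC + ECG

round(100 * c(acc = acc$mean$weighted_f1, acc_ecg = acc_ecg$mean$weighted_f1), 2)
#>     acc acc_ecg
#>   81.87   98.43
round(100 * rbind(acc = acc$mean$per_class_f1, acc_ecg = acc_ecg$mean$per_class_f1), 1)
#>         cycling sitting stairs table_soccer walking
#> acc         100     100   56.1          100    53.3
#> acc_ecg     100     100   96.6          100    95.6
```

Read: with the accelerometer alone, the cross-subject model scores 81.9%
weighted F1, and the damage is concentrated exactly where expected —
walking (53.3%) and stairs (56.1%) are confused with each other while
the other three activities are clean. Adding ECG features lifts the pair
to ~96% each and the overall score to 98.4%. PPG, the noisiest channel,
helps little (`scenario_id = 5` scores 81.9%, indistinguishable from ACC
alone). Subject-specific models (`subject_specific_cohort_eval`) sit
higher than LOSO throughout, since they never face an unseen person.

A thin CLI over the same functions is installed at
`inst/cli/fusionhar` (`simulate`, `features`, `evaluate`, `sweep`).

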