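# pdmotor

Objective assessment of the two cardinal motor signs of Parkinson's
disease — tremor and bradykinesia — from a wrist-worn 6-axis inertial
sensor (3-axis accelerometer in G, 3-axis gyroscope in degrees per
second, sampled at 100 Hz during standard 60-second clinical tasks).
`pdmotor` implements the complete analysis pipeline a movement-disorders
study of this kind needs, for researchers and engineers working with
wearable IMU data:

1. **Synthetic cohort generation** — labeled 6-axis recordings for a
   configurable study (default 20 healthy / 10 tremor / 10 bradykinesia
   subjects) with class-specific motion models: narrowband rest tremor at
   4–6 Hz, brisk ~3 Hz voluntary tapping for healthy subjects, and
   slowed, attenuated, within-trial-decaying movement for bradykinesia,
   plus sensor noise, random-walk drift and outlier spikes.
2. **Preprocessing** — Hampel outlier removal (11-sample window, 3 scaled
   MADs) followed by a zero-phase 10th-order Butterworth band-pass,
   2–20 Hz, which passes every clinically relevant tremor band and
   removes DC, gravity and drift.
3. **Feature extraction** — 11 features per channel (66 per subject):
   mean, SD, RMS, Pearson kurtosis, skewness, peak value; approximate
   entropy ApEn(m, r) = Φ_m(r) − Φ_{m+1}(r) (Pincus, m = 2,
   r = 0.2·SD) and the Grassberger–Procaccia correlation dimension
   (slope of log C(r) vs log r in a delay embedding); Welch/Hamming
   spectral peak amplitude, peak frequency, and 4–6 Hz band power.
4. **Feature ranking** — one-way ANOVA F across the three classes
   (F = MS_between / MS_within), normalized importance scores, top-k
   selection (default k = 24).
5. **Classification** — supervised KNN (k = 10, standardized Euclidean,
   30% stratified hold-out) and an unsupervised 3-neuron batch-trained
   self-organizing map evaluated by quantization MSE, both reported with
   the full confusion-matrix surface: accuracy, PPV/FDR, TPR/FNR,
   per-class sensitivity/specificity, and one-vs-rest ROC curves.

Everything is tidyverse-native: functions take and return tibbles,
results have `tidy()` / `glance()` methods and `autoplot()` figures, and
the whole study runs from one `pipeline_config()`.

## Worked example

```r
library(pdmotor)

res <- run_pipeline(pipeline_config(cohort = cohort_spec(), seed = 1),
                    out_dir = "runs/demo")

head(tidy(res$ranking), 4)
#> # A tibble: 4 x 5
#>   feature     F  p_value normalized_score  rank
#>   <chr>   <dbl>    <dbl>            <dbl> <int>
#> 1 ax_apen  195. 2.18e-20            1         1
#> 2 az_apen  193. 2.65e-20            0.989     2
#> 3 ay_apen  191. 3.12e-20            0.979     3
#> 4 gz_apen  102. 9.05e-16            0.521     4

res$summary$knn_accuracy      # hold-out accuracy of KNN (12 test subjects)
#> [1] 1
res$summary$som_correct_count # subjects the 3-neuron SOM assigns correctly
#> [1] 39
print(res$knn_report)
#> <pd_eval_report> accuracy 100.0% (12/12)
```

The approximate-entropy features lead the ANOVA ranking — regular
narrowband tremor is far more predictable than healthy or bradykinetic
movement — followed by the other nonlinear and spectral features; the
reduced 24-feature table separates the three classes cleanly for both
classifiers. `autoplot(res$ranking)`, `autoplot(res$knn_report)` and
`plot_feature_histograms()` visualize the ranking, the ROC curves and
the class overlap per feature.

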