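# eegkata

Connectivity analysis and a convolutional soft sensor for 14-channel
EEG recorded during two lean-management problem-solving routines:
**KATA** (goal-fixed; sub-tasks of 10/40/250 s) and **(CPD)nA**
(Check-Plan-Do; 10/250/40 s). The package is aimed at researchers who
want a fully reproducible, tested re-implementation of this analysis
that runs end-to-end on synthetic data with a known ground truth.

It provides:

* a **synthetic EEG generator**: independent unit-variance band-limited
  (4–30 Hz) latent sources, linear mixing, broadband noise and
  low-frequency drift, with a closed-form correlation oracle
  `corr(i,j) = w_i·w_j / sqrt((w_i·w_i + σ_i²)(w_j·w_j + σ_j²))`.
  Regime presets reproduce the reported coupling structure: frontal
  pairs ≥ 0.45, (F7,F3)/(F4,F8) ≥ 0.85, temporoparietal–frontal pairs
  in [0.21, 0.34] under KATA and [0.68, 0.73] under (CPD)nA;
* **causal preprocessing**: forward-only 5th-order Butterworth 1 Hz
  high-pass and 50 Hz low-pass, per-channel [0,1] normalization, 1-s
  segmentation with sub-task labels;
* **connectivity**: zero-lag cross-correlation matrices and the four
  region-coupling hypotheses H1–H4 with inclusive thresholds;
* an **RGB encoder** mapping each 1-s segment to a 5 × 128 image
  (channel triplets as pixel rows, samples as columns, 8-bit values);
* a **convolutional soft sensor** (built from scratch in vectorized R:
  im2col convolution, max pooling, Adam) classifying encoded segments
  as KATA vs (CPD)nA, with per-channel shallow features (mean, sd,
  theta/alpha/beta band power) merged at the dense layer and accuracy
  `ACC = (TP+TN)/(TP+TN+FP+FN)` reported with the confusion matrix;
* a **pipeline** tying it all together from a YAML config, with a
  subject-wise 80/10/10 split (20/2/2 at 24 subjects) that makes
  segment-level leakage impossible.

## Worked example

```r
library(eegkata)

# one synthetic subject per task, preprocessed
kata  <- simulate_recording(make_regime_config("KATA",  seed = 11),
                            kata_script(),  fs = 128, seed = 21)
cpdna <- simulate_recording(make_regime_config("CPDnA", seed = 11),
                            cpdna_script(), fs = 128, seed = 22)
cm_k <- correlation_matrix(subtask_window(preprocess(kata),  "KATA-III"))
cm_c <- correlation_matrix(subtask_window(preprocess(cpdna), "Plan"))

round(c(F7F3 = cm_k["F7","F3"], P8F8_kata = cm_k["P8","F8"],
        P8F8_cpdna = cm_c["P8","F8"]), 3)
#>      F7F3  P8F8_kata P8F8_cpdna
#>     0.874      0.285      0.714

reports <- evaluate_hypotheses(cm_k, cm_c)
vapply(reports, `[[`, "", "verdict")
#> "supported" "supported" "supported" "supported"
```

The within-hemisphere frontal pair F7–F3 is strongly coupled in both
tasks (0.874 ≥ 0.85, H2), while the right temporoparietal–frontal pair
P8–F8 separates the routines: 0.285 (≤ 0.34, H3) under KATA versus
0.714 (≥ 0.68, H4) under (CPD)nA — weak versus strong
context-dependent coupling. All four hypotheses are supported on the
regime presets.

The full experiment — 24 subjects, 12,000 images, training and
held-out evaluation of the soft sensor — runs from one config:

```r
report <- run_pipeline(read_run_config(
  system.file("config", "default.yaml", package = "eegkata")))
report$metrics$ACC   # held-out subject accuracy, e.g. 0.992
```

A 4-subject smoke configuration (`config/smoke.yaml`) completes in
about two minutes.

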