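---
title: "Methods: synthetic regime EEG, coupling hypotheses, and the convolutional soft sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic regime EEG, coupling hypotheses, and the convolutional soft sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`eegkata` analyzes 14-channel scalp EEG recorded while process owners
execute two lean-management problem-solving routines: **KATA**, a
goal-fixed routine (sub-tasks KATA-I/II/III of 10, 40 and 250 s), and
**(CPD)nA**, a Check-Plan-Do routine with directional improvement but no
fixed target (Check/Plan/Do of 10, 250 and 40 s). Sessions last 300 s at
128 samples/s on the 14-sensor AES montage (AF3, F7, F3, FC5, T7, P7,
O1, O2, P8, T8, FC6, F4, F8, AF4).

The neurophysiological contrast between the routines is expressed as
four sensor-coupling hypotheses over zero-lag cross-correlations:

* **H1** — all 15 pairs among the six frontal sensors (AF3, F7, F3,
  AF4, F4, F8) correlate at &ge; 0.45 in both tasks (executive
  engagement of the prefrontal cortex);
* **H2** — the within-hemisphere pairs (F7,F3) and (F4,F8) correlate at
  &ge; 0.85 (coordinated dorsolateral/ventromedial PFC activity);
* **H3** — in KATA, the temporoparietal-junction-to-frontal pairs
  (P7,F7), (P7,F3), (P8,F4), (P8,F8) stay &le; 0.34 (context-independent
  processing);
* **H4** — in (CPD)nA the same pairs reach &ge; 0.68 (context-dependent
  processing).

On top of the hypothesis analysis, a convolutional *soft sensor*
classifies individual 1-s segments, encoded as small RGB images, as KATA
vs (CPD)nA.

Because the original subject recordings are not redistributable, the
package ships a synthetic-data generator whose presets encode exactly
these coupling regimes; every downstream stage is developed and tested
against it.

## The generator and its closed-form oracle

Channels arise from independent, unit-variance, band-limited (4–30 Hz)
Gaussian latent sources by linear mixing, plus per-channel broadband
Gaussian noise and a low-frequency random-walk drift. For mixing weights
$w_i$ and noise scale $\sigma_i$ the zero-lag channel correlation is

$$\rho_{ij} = \frac{w_i \cdot w_j}
 {\sqrt{(w_i\!\cdot\!w_i + \sigma_i^2)(w_j\!\cdot\!w_j + \sigma_j^2)}},$$

which `analytic_channel_correlation()` evaluates exactly. This closed
form is the test oracle: empirical correlations of a preprocessed 250-s
simulated window must match it entrywise within ±0.05 (in practice they
agree within ~0.02).

The mixing weights are constructed in closed form from a structured
factor model rather than by numerical optimization: one *global frontal*
source (loadings 0.75 on AF3/AF4, 0.72 on F7/F3/F4/F8), one *pair*
source per hemisphere whose loading is set so that corr(F7,F3) =
corr(F4,F8) = 0.88, and one private source per channel topping every
variance up to $1-\sigma^2$ (noise fraction $\sigma^2 = 0.05$). P7 and
P8 load on their hemisphere's (global, pair) sources proportionally, so
that corr(P7, F7/F3) and corr(P8, F4/F8) equal the regime target
exactly: 0.275 for KATA (interval [0.21, 0.34]), 0.705 for (CPD)nA
(interval [0.68, 0.73]), 0 for the control preset. The construction is
exact, so a least-squares solve would only add numerical error; this is
the one place the implementation deliberately simplifies the original
plan of fitting weights numerically.

Numerical margins motivated the frontal loadings: the smallest analytic
frontal-pair correlation is $0.72^2 = 0.5184$, far enough above the 0.45
bound that sampling error of a 250-s window (s.d. ≈ 0.007) cannot cross
it.

Per-subject variability is a ±0.02 uniform jitter on the target
correlations, truncated to the regime interval, so every simulated
subject stays inside the printed ranges. Session-length windows give
effective sample sizes of roughly $2 \times 26\,\text{Hz} \times 250\,
\text{s} \approx 13{,}000$, so empirical coefficients concentrate
tightly around their targets.

What the generator does *not* emulate: eye-blink/EMG artifacts,
non-stationarity across sub-tasks, volume-conduction spectra, or any
per-subject demographic structure. Passing tests therefore demonstrate
that the pipeline recovers the designed coupling structure — not that it
would survive artifact-laden field recordings.

## Preprocessing

Causal (forward-only) 5th-order Butterworth IIR filters: a 1 Hz
high-pass removes DC offset and drift, then a 50 Hz low-pass removes
high-frequency noise (this also subsumes the hardware 50 Hz notch).
Causality is a deliberate constraint — sample $t$ of the output depends
only on inputs at or before $t$ — verified by a front-padding property
test. Butterworth was chosen for its monotone, flat passband; the order
mirrors the recording hardware's 5th-order filtering stage.

Normalization maps each channel onto [0, 1] by min–max scaling over the
*whole recording* (not per segment): an affine map per channel that
preserves rank order and inter-channel correlation while discarding
absolute amplitude, which is both privacy-preserving and
subject-anonymizing. Whole-recording scope follows the processing order
of the original description (normalization precedes segmentation);
per-segment scaling would change image contrast segment by segment.

Segmentation cuts non-overlapping 1-s windows (128 samples), drops any
trailing partial window, and labels each segment with the sub-task
interval containing its *start* sample.

## Connectivity

`cross_correlation()` is the normalized zero-lag inner product of the
mean-removed signals — the Pearson coefficient — with an optional
maximum-magnitude search over lags in $[-L, L]$, off by default: the
hypothesis thresholds refer to the zero-lag definition, and the lag at
which printed coefficients were read is not stated, so the stricter
zero-lag choice is used. Coefficients are computed on the full 250-s
analysis window (KATA-III, Plan), one coefficient per pair per task, not
averaged over 1-s segments. Threshold comparisons are inclusive
(boundary equality passes). Per-pair coefficients are always reported
alongside verdicts since coupling strength legitimately varies across
pairs.

## Image encoding

Channels are grouped three at a time in montage order — [AF3,F7,F3],
[FC5,T7,P7], [O1,O2,P8], [T8,FC6,F4], [F8,AF4,∅] — one triplet per
pixel row, members mapped to the red/green/blue planes; column $t$ holds
sample $t$. A 1-s segment therefore becomes a 5 × 128 RGB image.
Values, already in [0, 1], are quantized to 8 bits by round-half-up
(`floor(255 v + 0.5)`); the padded null channel encodes 0, keeping the
blank plane visually distinct. The triplet assignment and the null
padding are package decisions (the original description fixes neither);
they are deterministic and documented, and `decode_image()` inverts the
encoding within one quantization step (≤ 1/255 per value), which the
round-trip tests enforce.

Only KATA-III and Plan segments enter the classifier dataset: 24
subjects × 2 tasks × 250 s × 1 s⁻¹ = 12,000 images, 6,000 per class —
the only composition consistent with the study's printed dataset size.

## The soft sensor

Architecture: `[conv → max-pool → ReLU] × 2 → flatten → concat(shallow
features) → dense(128, ReLU) → softmax`, with 32 then 64 filters, 3 × 3
kernels (clipped to the remaining height) and 2 × 2 max pooling
(falling back to height-1 pooling once the map is a single row). Since
max pooling commutes with the monotone ReLU, the implementation pools
before rectifying — identical outputs, less arithmetic. Shallow
features are, per channel: mean, standard deviation, and periodogram
band power in theta (4–8 Hz), alpha (8–13 Hz) and beta (13–30 Hz) — 70
values for 14 channels — merged at the dense layer. Training uses Adam
(learning rate 10⁻³), batch 32, 10 epochs, softmax cross-entropy; the
weights of the epoch with best validation accuracy are kept (earliest
epoch on ties, reflecting the early plateau typical of this task). All
randomness — initialization, shuffling, splitting — flows from explicit
integer seeds; identical seeds give identical models. The layer sizes
are package defaults chosen as the smallest configuration that cleanly
separates the synthetic regimes on a single CPU; the published
architecture diagram fixes the block sequence but not the sizes.

**Input instance normalization.** Before the first convolution, each
channel plane of each image (and, consistently, the shallow-feature
vector: mean → 0, sd → 1, band powers → band-power/variance) is
standardized over its 1-s window. Rationale: the per-recording min–max
normalization leaves an arbitrary affine gain and offset per channel
that varies from recording to recording and acts as a *recording
fingerprint*; a network trained on raw encoded pixels can reach perfect
training accuracy by memorizing these fingerprints and then fails to
generalize to held-out subjects. Zero-lag correlation — the quantity
that actually separates the behavioral patterns — is invariant to
positive affine maps per channel, so standardizing removes the nuisance
without touching the signal. Empirically this layer is what lifts
held-out-subject accuracy from ~0.70 to ≥ 0.99; it is on by default and
is an architecture choice of this package.

The subject-wise 80/10/10 split (20/2/2 at 24 subjects) assigns whole
subjects to partitions; evaluation refuses any subject overlap with the
training set, so segment-level leakage is impossible by construction.
Accuracy is reported as ACC = (TP+TN)/(TP+TN+FP+FN) with KATA as the
positive class, alongside the 2 × 2 confusion matrix and per-class
rates.

## Problem sizes used by the test suite

The checks run at the following scales, chosen to exercise the full
study design where the claim depends on it and smaller cohorts
elsewhere: structural counts (12,000 images; 20/2/2 split) and the
classifier criterion use the full 24-subject cohort, the latter across
three split/initialization seeds on the fixed study cohort — the random
element of the original evaluation is precisely the choice of held-out
subjects; connectivity recovery uses single subjects with 250-s
analysis windows; unit tests of training mechanics use a 4-subject
cohort; the null experiment (control-vs-control, no class difference,
held-out accuracy required to stay within [0.4, 0.6]) uses 8 subjects
and 6 epochs. Smaller cohorts were also evaluated for the classifier
criterion: at 12 subjects held-out accuracy reaches only 0.97–0.98 (ten
training subjects do not span enough recording variability), which is
why that criterion is pinned to the full design.

## Degenerate inputs and numerical choices

Constant channels are rejected by name at normalization (their range is
empty) and at correlation (zero variance). Cutoffs at or above Nyquist,
recordings shorter than the 2-s filter warm-up, pooling wider than the
feature map, unknown regime labels, unknown channels and ratio vectors
not summing to 1 are all hard errors. Segment/window arithmetic is
integral by construction (`window_s × fs` must be whole). The
mixing-weight construction validates that private variances stay
non-negative. No silent resampling or channel imputation anywhere:
sampling-rate or montage mismatches on file input are errors.

## Known limitations

* The generator's stationarity means sub-task boundaries carry no
  signal; segment labels come from the task script alone.
* Artifact handling (blinks, EMG) is out of scope; on real recordings
  the pipeline would need an artifact-rejection stage before the
  correlations are interpretable.
* Inter-subject comparisons are deliberately unsupported (per-recording
  normalization erases the scale needed for them).
* EDF input is not implemented; cohorts are exchanged as CSV plus a
  JSON manifest.
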