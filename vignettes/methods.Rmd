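---
title: "Detecting fetal arrhythmia from abdominal ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fetal arrhythmia from abdominal ECG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fetal arrhythmia — broadly, fetal heart rates above 180 bpm (tachycardia) or
below 100 bpm (bradycardia), or irregular rhythm — is a risk factor for
fetal death that is treatable when caught early. The non-invasive route to
the fetal heartbeat is the abdominal ECG (AECG): electrodes on the maternal
abdomen record a mixture in which the maternal ECG dominates, the fetal ECG
(FECG) is small, and noise is substantial. Classical detectors first
estimate fetal R-peaks and then classify subjects from features of the
beat-to-beat (RR) intervals, which makes the diagnosis only as good as the
peak detector. `fetalarr` implements the alternative this package is built
around: classify raw FECG *waveform segments* with a small convolutional
network, use RR-interval statistics only to *label the training data*, and
decide at the subject level by voting over many segments. Labeling errors
from imperfect beat detection then dilute the training signal instead of
corrupting each test decision.

## Pipeline

1. **Preprocess** (`preprocess`): saturated runs (samples pinned at
   ≥ 99.9 % of the observed dynamic range for ≥ 50 ms) and non-finite
   samples are masked invalid; each channel is band-passed 3–45 Hz
   (zero-phase Butterworth, order 3); 1 kHz records are decimated to
   500 Hz, the rate every later stage assumes. Records more than half
   invalid are rejected.
2. **Maternal R-peaks** (`detect_maternal_rpeaks`): Pan–Tompkins on the
   maternal thoracic channel (or the abdominal channel with the most
   5–15 Hz energy): band-pass 5–15 Hz, five-point derivative, squaring,
   150 ms moving-window integration, adaptive signal/noise thresholds with
   a 200 ms refractory period. Peak times are refined to the midpoint of
   the extremum pair of the band-passed complex, which is stable for
   biphasic waveforms where the single largest lobe is not.
3. **Maternal removal** (`subtract_maternal_template`): per channel, beat
   windows −250…+450 ms around each maternal R-peak are averaged into a
   template (edges linearly tapered over 25 ms), scaled per beat by least
   squares, and subtracted. The abdominal channel whose residual has the
   highest 10–40 Hz excess kurtosis — the spikiest remaining fetal
   content — becomes the FECG. Which abdominal lead best exposes the fetus
   varies with electrode placement, so the choice is data-driven.
4. **Fetal R-peaks** (`detect_fetal_rpeaks`): candidates are local maxima
   of the smoothed absolute first derivative above an adaptive per-5 s
   threshold. Greedy left-to-right acceptance scores each candidate by
   amplitude times a Gaussian prior `exp(−(Δt−μ)²/2σ²)` on the elapsed
   interval, with running estimates (μ, σ) initialized at (400, 50) ms —
   the fetal RR prior — updated by exponential smoothing, a 200 ms
   refractory period (a 300 bpm ceiling, above any reported fetal rate),
   and an amplitude gate at 0.4× the running median accepted amplitude.
   Two guards keep the prior honest at both rhythm extremes. The Gaussian
   weight carries a small additive floor (0.05) so that a genuinely long
   arrhythmic interval, whose next true peak sits far from μ, can still
   beat sub-gate noise; without the floor the prior inserts spurious
   beats at μ during bradycardic runs. Symmetrically, a skip penalty
   subtracts (at weight 0.5) the amplitude of every strong candidate a
   later pick would jump over — every real QRS should be consumed — since
   without it the prior prefers the skip-one interval (~480 ms) over a
   true tachycardic beat (~240 ms) and silently halves fast rhythms.
5. **RR intervals** (`compute_rri`): successive differences, gated to
   100–900 ms — the support over which pooled fetal RRI histograms carry
   mass; anything outside is a detection artifact.
6. **Segmentation** (`segment_signal`): 3 s windows, 1 s step
   (`floor((T−3)/1)+1` segments of exactly 1500 samples at 500 Hz). A
   window owns an RR interval only when *both* defining peaks fall inside
   it, so every label is supported by waveform evidence inside the window;
   windows touching invalid samples are dropped, and windows with fewer
   than two owned intervals are treated as moderate (they signal detection
   failure, not rhythm).

## Labeling from the pooled RRI histogram

All healthy-subject and all arrhythmia-subject intervals are pooled into
25 ms bins from 100 to 900 ms (`build_rri_histogram`). For each bin the
ratio healthy/arrhythmia counts is classified (`classify_rri_ranges`):

* **N** (normal) when the ratio exceeds 1 — healthy intervals outnumber
  arrhythmic ones (a bin with healthy counts only has ratio ∞ and is N);
* **A** (arrhythmic) when the ratio is *strictly* below the threshold `x`;
* **M** (moderate) when `x ≤ ratio ≤ 1`;
* unobserved bins (both counts zero) are excluded from training and
  treated as moderate at inference — there is no evidence either way.

The strict inequality is deliberate: published range tables of this scheme
classify a bin whose ratio exactly equals `x` as moderate, although the
accompanying prose says "lower than or equal to". The bundled reference
table (`reference_rri_ranges()`) contains the discriminating row (ratio
0.5000 at `x = 0.50` → M), and the package follows the table. A ratio of
exactly 1 is likewise read as "not more healthy than arrhythmic", i.e. M.

Segments inherit labels with precedence arrhythmia > moderate > normal
over their owned intervals (`label_segments`). Two refinements matter:

* an arrhythmia-labeled segment from a *healthy* subject is reassigned to
  moderate — the interval evidence contradicts the subject's record, so
  the segment must not teach either class;
* moderate segments are excluded from binary training entirely
  (`build_training_set`): they are compatible with both origins and would
  blur the boundary.

The default `x = 0.63` reproduces the published operating point; sweeps
over `x ∈ {0.50, 0.60, 0.63, 0.65, 0.70}` are supported throughout.

### Per-subject variant

The per-subject labeling variant (`subject_band`, `calibrate_y`,
`label_segments_per_subject`) replaces the cohort histogram with each
arrhythmia subject's own band `mean ± y·SD` (population SD; the sample/
population choice is unstated in the source material, so one was fixed for
reproducibility): intervals inside the band are moderate, outside
arrhythmic, and healthy subjects' segments are all normal. `y` is
calibrated by bisection (tolerance 1e-4) to the smallest value for which a
target fraction (50–90 %) of the subject's intervals is moderate. The
classifier then runs with three classes, and the subject ratio becomes
`ARR/(ARR+NR)`, ignoring moderate-classified segments
(`subject_ratio_ternary`).

## The segment classifier

A deliberately small 1-D CNN (`cnn_config`, `train_cnn`, `predict_cnn`):
two blocks of convolution + ReLU + max-pool, a dense ReLU layer, and a
softmax output; cross-entropy loss (binary or categorical) with
inverse-frequency class weights; Adam at learning rate 3e-4 — the one
published optimizer setting. The published architecture figure does not
recover filter counts, kernel sizes, pooling widths, dense width, epochs
or batch size, so those defaults are declared here, not claimed to match:
8 then 16 filters, kernel 15 samples (30 ms — the scale of a fetal QRS),
max-pool 6, dense 32, 12 epochs, batch 128. Full temporal resolution in
the convolutions with aggressive pooling between blocks outperformed a
strided first convolution of equal cost on held-out subjects, so the
stride option defaults to 1. They were chosen once as the
smallest architecture that cleanly separates the synthetic benchmark
(99 %+ training accuracy on clean rhythm classes) and are all
configurable. Segments are z-scored individually so electrode-dependent
amplitude cannot act as a class cue. The network is implemented in the
package itself (im2col + BLAS matrix products, with compiled layer
primitives; gradients verified against finite differences in the tests)
and is deterministic given its seed.

## Subject decision and evaluation

The binary subject statistic is the fraction of *all* segments the CNN
calls arrhythmia (`subject_ratio_binary`) — labels are a training device,
so no segment is excluded at inference; a subject is arrhythmic when the
ratio strictly exceeds `th` (`classify_subject`), swept over 0.00–1.00 in
0.05 steps. Metrics are specificity TN/(TN+FP), recall TP/(TP+FN) and
accuracy (TP+TN)/all, with zero denominators reported as `NA` rather than
silently zeroed (`compute_metrics`).

Evaluation is leave-one-subject-out (`loso_evaluate`): for each fold the
RRI histogram, the bin classes and all training labels are rebuilt from
the remaining subjects only, so nothing derived from the held-out subject
— not even its contribution to the pooled histogram — can leak into its
own fold. The evaluation protocol behind the published headline numbers
is unstated; LOSO is the defensible choice for a 26-subject cohort, and
this package makes no claim of reproducing those headline numbers (they
also require the real PhysioNet recordings).

## The synthetic cohort

`nifeadb_like_cohort` + `simulate_cohort` emulate the public
fetal-arrhythmia database layout: 14 healthy and 12 arrhythmic subjects,
4–5 abdominal channels plus one maternal thoracic channel, 500 Hz (or
1 kHz). Per subject:

* **Healthy RRIs**: i.i.d. truncated normal, mean jittered U(385, 415) ms
  around the 400 ms cluster of real fetal recordings, SD U(28, 40) ms
  around the 33.94 ms pooled anchor, clipped to 200–700 ms.
* **Arrhythmic RRIs**: same baseline plus Poisson-arriving sustained
  runs during which intervals are substituted uniformly from an episode
  range. Abnormal rhythm dominates the recording: two-thirds of subjects
  spend ~60 % of beats in 20-beat bradycardic runs at 430–560 ms,
  one-third ~50 % in 30-beat SVT-like tachycardic runs at 290–360 ms,
  with normal rhythm in between. The duty cycles and ranges come from
  closed-form mixture arithmetic targeting the published facts jointly:
  the ~72 ms pooled arrhythmia SD (realized 71.5 ms at the benchmark
  scale, healthy 34.9 ms); the wide, bimodal pooled histogram whose
  range-ratio column shows heavy arrhythmic mass from ~475 ms up and
  below ~350 ms with normal bins at 350–450 and a moderate boundary bin
  at 450–475 (the realized synthetic table reproduces that structure);
  and the observation that real cohorts pair healthy
  arrhythmia-segment ratios of 0.3–0.4 with high-specificity operating
  thresholds of 0.6–0.75, which requires arrhythmic subjects to be
  abnormal most of the time. An "occasional-ectopic" model with rare
  episodes matches the SD scalar but none of the distributional
  structure the labeling scheme depends on. A gated substitution model
  was chosen over an autoregressive one because it has interpretable
  knobs (rate, run length, range) and arrhythmia in real traces comes in
  bouts, not slow drifts.
* **Waveforms**: fetal QRS = biphasic difference-of-Gaussians template,
  width 40 ms, unit amplitude — fetal complexes are narrow and the
  classifier needs no P/T morphology; maternal QRS = the same template at
  80 ms width and 4× amplitude on a regular 75 bpm train; baseline wander
  = sinusoids below 0.8 Hz (exercising the 3 Hz high-pass); white noise
  at 10 dB fetal SNR. The source material states no SNR or noise model
  for its recordings, so 10 dB is an engineering default, not a recovered
  fact.

What the generator does *not* emulate — fetal movement artifacts,
electrode-specific lead fields, maternal heart-rate variability, P/T
waves, real muscle/powerline noise — bounds what passing tests show: they
validate the machinery (labeling logic, training protocol, decision
statistics, end-to-end parameter recovery) under the stated statistical
structure, not clinical performance on real recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run the cohort at 60 s per
subject (the package's benchmark scale; ~58 segments per subject,
~1500 segments over the cohort), the recording-scale default in
`subject_spec` being 600 s. Parameter-recovery checks compare detected
interval statistics against the *realized* ground-truth sequence from the
simulator sidecar, not against the generator's nominal mean — an
arrhythmic subject's realized mean is shifted by its episodes, and the
detector can only recover what was generated. Bisection tolerances
(1e-4 on `y`), the RR-prior clamps (σ ∈ [30, 90] ms), the candidate gate
(0.25× the 90th-percentile envelope per 5 s block) and the filtfilt edge
trim (250 ms) are stated in the function documentation; ties in max-pooling
resolve to the earliest position; softmax is computed with the row-max
subtracted for stability; a training loss that turns non-finite aborts
with a diagnostic rather than continuing.

## Known limitations

* The WFDB support is the minimal format-16 subset the cohort writer
  emits; annotation files and other signal formats are out of scope.
* The fetal detector uses a single Gaussian RR prior; the multi-weighting
  refinements of dedicated fetal HR estimators are not reproduced.
* Segment classification feeds on one abdominal channel (the
  kurtosis-selected residual); multi-channel fusion is not implemented.
* Real-data performance claims are out of scope desk-side: the package's
  quantitative guarantees are the reproduced published tables/ratios and
  the synthetic-cohort benchmarks computed by `scripts/acceptance.R`.
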