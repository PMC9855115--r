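# fetalarr

Fetal arrhythmia detection from non-invasive abdominal ECG.

Fetal arrhythmia — heart rates above 180 bpm (tachycardia), below 100 bpm
(bradycardia), or irregular rhythm — is a treatable risk factor for fetal
death, and the abdominal ECG (AECG) is the accessible way to monitor it:
electrodes on the maternal abdomen record a mixture dominated by the
maternal ECG in which the fetal ECG (FECG) is small and noisy. Classical
detectors classify subjects from features of the estimated fetal RR
intervals (RRIs), so their accuracy collapses with the beat detector's.
`fetalarr` implements the alternative strategy this package is built
around, for researchers working with recordings like PhysioNet's
non-invasive fetal arrhythmia database (nifeadb): classify raw FECG
*waveform segments* with a small 1-D CNN, use RRI statistics only to
*label the training data*, and decide per subject by voting over segments.

The core procedure:

1. Extract the FECG: band-pass 3–45 Hz, resample to 500 Hz, detect
   maternal R-peaks (Pan–Tompkins), subtract a per-beat-scaled maternal
   template, then detect fetal R-peaks by weighting derivative candidates
   with a Gaussian RR prior, `exp(-(Δt-μ)²/2σ²)` with running (μ, σ)
   initialized at (400, 50) ms.
2. Cut the FECG into 3 s windows with 1 s step (1500 samples each).
3. Pool all subjects' RRIs into 25 ms bins and classify each bin from the
   healthy/arrhythmia count ratio *r*: normal (N) if r > 1, arrhythmic
   (A) if r < x (default x = 0.63), moderate (M) otherwise. Segments
   inherit labels with precedence A > M > N over the intervals they
   contain; moderate segments are excluded from training, and
   arrhythmia-labeled segments of healthy subjects are reassigned
   moderate.
4. Train the CNN (conv–ReLU–pool ×2, dense, softmax; Adam, lr 3e-4) on
   normal vs arrhythmia segments; classify every segment of a test
   subject; call the subject arrhythmic when the fraction of
   arrhythmia-classified segments exceeds a threshold th, swept over
   0.00–1.00 in 0.05 steps. Metrics: specificity TN/(TN+FP), recall
   TP/(TP+FN), accuracy (TP+TN)/all.
5. A per-subject variant labels each arrhythmia subject's intervals
   against their own band mean ± y·SD (y calibrated so 50–90 % of
   intervals are moderate), trains a ternary classifier, and uses the
   ratio ARR/(ARR+NR).

A synthetic cohort simulator (WFDB output, ground-truth sidecars)
reproduces the statistical structure the method assumes — healthy RRIs
clustered near 400 ms (SD ≈ 34 ms), arrhythmic ones widely spread
(SD ≈ 72 ms) through bradycardic and tachycardic episode substitution —
so the whole pipeline is testable without downloads.

## Worked example

```r
library(fetalarr)

# simulate one healthy + one arrhythmic subject (60 s, 500 Hz)
spec <- nifeadb_like_cohort(n_healthy = 1, n_arrhythmia = 1,
                            duration = 60, seed = 42)
records <- simulate_cohort(spec)
records[[2]]
#> <aecg_record> a01: 5 ch x 30049 samples @ 500 Hz (60.1 s), class=arrhythmia
#>   channels: abd1[abd] abd2[abd] abd3[abd] abd4[abd] thoracic[mat]

# full extraction chain: preprocess -> maternal removal -> fetal peaks
ex <- extract_fecg(records[[2]])
ex$rris
#> <rri_series> a01 (arrhythmia): 129 intervals, mean 456.2 ms, sd 56.1 ms

# 3 s / 1 s segmentation and histogram-based labeling at x = 0.63
segs <- segment_signal(ex$fecg, ex$rris)
segs
#> <segment_set> 58 segments x 1500 samples (a01)
tab <- classify_rri_ranges(
  build_rri_histogram(list(extract_fecg(records[[1]])$rris, ex$rris)),
  x = 0.63)
table(label_segments(segs, tab))
#>     normal   moderate arrhythmia
#>         12          5         41
```

The arrhythmic subject's 60 s trace yields 58 overlapping segments: 41
contain at least one interval from an arrhythmia-dominated bin (the
subject's bradycardic runs), 12 contain only normal-bin intervals (the
stretches of normal rhythm between runs), and 5 are moderate — exactly
the "arrhythmia does not always occur" structure the moderate-exclusion
labeling is designed for. `loso_evaluate()` runs the leave-one-subject-out
protocol (per-fold histogram rebuild, training, threshold sweep) and
`cmd_simulate()` / `cmd_run()` (or the `inst/cli/fetalarr` script) do the
same from the command line.

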