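---
title: "Detecting aggressive shaking from wearable IMUs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aggressive shaking from wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbsdetect)
```

## The problem and the model

Violent shaking of an infant produces large, fast oscillations of the whole
body that routine caregiving (rocking, burping, diaper changes) does not.
`sbsdetect` classifies short windows of body-worn accelerometer data as
aggressive or non-aggressive movement. The classifier is deliberately
minimal — a depth-2 decision tree on 11 descriptive statistics of the
acceleration norm — because the intended deployment is a low-power wearable
where inference cost and interpretability dominate.

The processing chain is segmentation (3 s windows, 1 s shared between
neighbours), norm computation (`sqrt(ax^2 + ay^2 + az^2)`, removing
dependence on mounting orientation), feature extraction, annotation-driven
labeling, and per-position training/evaluation on a stratified 70/30
split. All stages are deterministic given the configuration seed.

## What the synthetic generator emulates — and what it does not

The study protocol it emulates: 8 participants x 18 tasks x 6 sensor
positions, 15 s per task at 100 Hz, yielding 144 performed tasks (56
aggressive, 88 non-aggressive) and 864 recordings. Task risk classes
follow the prescribed activity list: tasks 2, 4, 6, 7, 8, 10 and 13 are
high-risk shaking, tasks 14-18 daily care, the rest light shaking.

The motion model is a gravity vector at a fixed random orientation per
recording, plus a sinusoid along the task's shake axis with per-cycle
amplitude and frequency jitter (±10 %), plus white noise (SD 0.05 g per
axis). Two tasks get distinctive signatures: the throw-and-catch contains
0.4 s free-fall dips (specific force near zero) followed by a catch
impulse, and the burping task adds brief patting impulses.

Key parameters and defaults (units of g and Hz):

| parameter | aggressive | light | daily care |
|---|---|---|---|
| oscillation amplitude | 3–6 g | 0.3–1.0 g | 0.1–0.5 g |
| oscillation frequency | 3–5 Hz | 1–2 Hz | 0.3–1 Hz |

The 2.5 g `threshold_g` plays the role of the training doll's LED feedback
(the doll signals when a harmful acceleration level is reached; its actual
threshold is unpublished, so this value is an artifact choice). The
amplitude ranges guarantee separation by construction at unit attenuation:
an oscillation that reverses sign reaches a peak norm of at least
`sqrt(gravity^2 + amp^2)`, so the aggressive worst case (3 g x 0.9 jitter)
peaks at 2.88 g > 2.5 g, while light movement is bounded by
1 g + 1.1 g + noise < 2.5 g. `motion_params()` enforces this at
construction, which is why invalid range combinations error immediately.

Position attenuation models transmissibility: trunk-driven shaking reaches
head/chest at 1.0, arms at 0.9, legs at 0.8; the two arm-swing tasks invert
this (arms 1.0, everything else 0.6). Attenuated limb recordings of an
aggressive arm swing can therefore peak *below* 2.5 g — the threshold
guarantee holds at the driven site, while per-position classifiers learn
their own thresholds from their own data.

What the generator does **not** emulate: real inter-participant style
variation beyond amplitude/frequency draws, multi-event recordings (each
simulated recording has exactly one annotation spanning it), soft-tissue
dynamics and sensor saturation, gyroscope channels, and any overlap in
feature space between classes. Consequently the end-to-end test — every
position at accuracy ≥ 0.90 and sensitivity ≥ 0.80 — demonstrates that the
pipeline's plumbing recovers a separable structure, not that the method
achieves any particular performance on real infant-handling data. The
published per-position numbers (accuracy 0.97–0.98, sensitivity 0.82–0.92)
come from the study's unreleased recordings and are reproduced here only
as the worked-example arithmetic on the printed head-sensor confusion
counts.

## Numerical and statistical conventions

* **Windowing.** "3 s windows with 1 s overlap" is read as adjacent windows
  *sharing* 1 s, i.e. a 2 s step — seven windows per 15 s recording. The
  alternative (1 s step) is inconsistent with the stated purpose of the
  overlap, that no information is lost *between adjacent windows*. Only
  complete windows are emitted; indices are 0-based half-open.
* **Labeling.** Maximum-overlap rule with a 50 % minimum-coverage floor;
  ties break toward non-aggressive so the rare class is never inflated by
  ambiguity. Error-flagged events never contribute.
* **Features.** Population formulas throughout (windows are complete
  objects, not samples of themselves): SD divides by n; skewness is the
  standardized third central moment, kurtosis the excess fourth, both
  defined as 0 on zero-variance windows to avoid NaNs reaching the tree.
  Percentiles interpolate linearly between order statistics
  (`quantile` type 7). "Average frequency" is implemented as the spectral
  centroid and "entropy" as the Shannon entropy (bits) of the normalised
  one-sided periodogram of the mean-removed window; both are standard
  readings in activity-recognition feature sets, testable on single tones
  (a pure 4 Hz tone gives average frequency 4.0 and entropy 0), and the
  only spectral processing is mean removal — no filtering or outlier
  rejection anywhere in the chain, preserving real-time applicability.
* **Tree.** Split candidates are midpoints between consecutive distinct
  sorted values; the impurity decrease is the parent Gini minus the
  size-weighted child Ginis. Ties break toward the lower feature index and
  then the smaller threshold, making fitting a pure function of the data.
  Leaf ties predict aggressive: in a safety application, ambiguity should
  favour sensitivity. Splits whose computed decrease is below 1e-12 are
  treated as no improvement to keep floating-point noise from fabricating
  splits of pure or constant nodes.
* **Split.** Stratified segment-level sampling with largest-remainder
  allocation hits the target training size exactly while holding each
  class within one row of its exact proportion. A participant-grouped
  split is also provided because windows overlap in time: a random
  segment-level split lets nearly identical windows of one recording land
  on both sides, which optimistically biases the evaluation. The default
  remains segment-level stratified, matching the study's apparent
  procedure; the grouped mode is the documented caveat.
* **Metrics.** Aggressive is the positive class everywhere: sensitivity is
  recall of aggressive, specificity recall of non-aggressive. Stored
  values are full precision; rounding (half away from zero, 2 decimals)
  happens only in the reporting layer, mirroring how published performance
  tables are printed.

## Problem sizes

The default configuration — the full 864-recording session, 1008 labeled
windows per position, six trees — runs in a few seconds. Module tests use
reduced protocols (1–2 participants, 1–2 positions); the oracle-equivalence
property checks the split search against brute-force enumeration on 200
random instances of up to 30 x 5.

## Known limitations

* Simulated classes are separable by construction, so held-out metrics on
  synthetic sessions saturate at 1.0; the pipeline cannot be used to
  forecast real-world error rates.
* The segment totals of the original study (5092 windows, 749 aggressive)
  are not derivable from 144 tasks x 7 windows under any single-sensor
  reading of the windowing, and are not targeted.
* No gyroscope features, ensembles, pruning, cost-sensitive weighting, or
  cross-validation — the analysis is a single stratified split feeding a
  single depth-2 tree per position, by design.
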