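---
title: "Ensemble and decoding analysis of reward-seeking calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble and decoding analysis of reward-seeking calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleseek)
```

## The scientific problem

Thalamostriatal projection neurons (paraventricular thalamus to nucleus
accumbens, PVT→NAc) act as a tonic "brake" on reward seeking: at the
population level they are inhibited when an animal presses a lever for
sucrose, and distinct ensembles within the population carry distinct
response motifs. ensembleseek implements the full analysis chain for this
kind of experiment — deep-brain two-photon calcium imaging through a GRIN
lens during head-fixed operant self-administration — from movie
registration and ROI trace extraction, through peri-event ensemble
clustering and behavioral decoding, to cross-session tracking and the
slice-electrophysiology metrics that characterise the underlying synapses.

Because the original in-vivo datasets are not redistributable at desk
scale, the package ships a synthetic-data generator that emulates the data
structure with planted ground truth. Every stage of the pipeline is
validated against that ground truth; the generator is therefore a
first-class, tested module, not a fixture.

## The operant schedule

A head-fixed session exposes two levers. An *active*-lever press, when
reinforced, triggers a tone cue (1.6 s) and, 3 s after the press, a sucrose
delivery (2 s), then starts a 20-s timeout during which pressing has no
programmed consequence. Sucrose deliveries may be capped per session (10,
20 or 40 on the acquisition ladder). Inactive-lever presses are logged and
never reinforced. `apply_schedule()` implements this as an event-by-event
walk; `generate_events()` feeds it homogeneous-Poisson candidate presses.

Conventions that the data cannot decide and we therefore fixed:

* The timeout interval is half-open, `[start, start + timeout_s)`: a press
  landing exactly at timeout end is reinforced. Numeric ties are resolved
  with a 1-ns tolerance so floating-point timestamp arithmetic cannot flip
  them. The schedule is verified exhaustively against a brute-force 1-ms
  timeline simulator in the test suite.
* A press counts as *reinforced* only if it delivers something. In
  extinction (no cue, no sucrose) presses have no consequence at all — no
  reinforcement flag and no timeout. In reinstatement the cue alone
  reinforces and the timeout runs from cue onset.
* The extinction criterion (`extinction_met()`) reads "pressing rate" as
  the daily press count, since sessions are fixed length: at least 10
  extinction days, and 2 of the last 3 days at or below 20% of the mean of
  the last two acquisition days.

## The synthetic fluorescence model

`generate_traces()` builds each neuron's trace as

```
F_i(t) = B · (1 − d · t/T)  +  a_i · s(t)  +  ε(t)
```

* `B` — baseline fluorescence (arbitrary units, default 1).
* `d` — *tonic decline fraction*: the within-session decline of basal
  fluorescence, linear from the first to the last frame (default 0.2;
  basal fluorescence is the proxy for tonic firing in these neurons).
* `a_i` — the neuron's ensemble amplitude: `+0.5` dF/F for excited cells,
  `−0.5` for inhibited cells, `0` for non-responders (defaults), scaled by
  `1 − drug_attenuation` to model acute pharmacological blunting.
* `s(t)` — a unit-peak response shape around every active press: a boxcar
  over `[onset, onset + duration]` convolved with a single-exponential
  calcium-indicator kernel (`τ = 0.6` s, GCaMP6m-like). The kernel is a
  modelling convenience — only the response shape matters for testing.
* `ε(t)` — i.i.d. Gaussian frame noise (default SD 0.2 dF/F).

The default population composition is 79 excited / 153 non-responding / 73
inhibited per 305 cells, mirroring the reported field-of-view composition;
`ensemble_spec_scaled()` rescales it by largest remainder.

Two defaults deserve justification:

* **Response onset −2 s (anticipatory).** Responses begin during lever
  approach, before the press itself. This is required for the decoding
  design to make sense: the decoder reads a 1-s epoch *before* each press
  precisely because pre-press activity is informative, and the peri-event
  z-scoring baseline deliberately stops at −5 s to stay clear of
  approach-related activity.
* **Trial-to-trial amplitude jitter, CV 0.2.** Single-trial variability of
  these neurons is uncharacterised; 20% multiplicative jitter is a
  conventional level of trial noise, not a claim about the data.

What the generator does *not* model: spiking or calcium-binding
biophysics, photobleaching, shot noise (noise is Gaussian), neuropil
contamination, or non-rigid motion. Tests passing on this generator
demonstrate the pipeline's correctness on data with the study's structure;
they do not certify performance on artifacts the generator omits.

## Imaging

`register_movie()` substitutes a deliberately simple rigid registration
for heavier motion-correction machinery: per-frame integer-pixel
translation estimated by FFT cross-correlation against the mean (or first)
frame, exposed pixels filled with the frame median. The scientific content
downstream does not depend on the registration algorithm, and the
substitute is verified by exact recovery of planted integer shifts.
Sub-pixel registration is intentionally omitted.

`extract_traces()` is the plain ROI mean over pixels; masks are inputs
(ROIs were drawn manually in the original workflow; no automatic
segmentation is attempted). `deltaf_normalize()` offers two
normalizations, because the convention for peri-event fluorescence is
genuinely ambiguous in this literature: per-neuron percentile dF/F
(default 10th percentile) and division by the first time bin. Both are
exposed; analyses state which they use.

## Peri-event tensors and ensembles

`build_peri_event_tensor()` aligns a 23-s window to each active press:
10 s before, the 3-s press-to-delivery interval, 10 s after. Trials
truncated by the session edge are excluded (never padded) and counted.
Each neuron is z-scored against its own baseline, the −10 to −5 s segment
pooled across trials; the segment ends at −5 s to exclude anticipatory
activity from the reference. Neurons with numerically zero baseline SD
(possible only in noiseless synthetic data) fall back to unit SD.

Components are selected on the trial-averaged neuron × timepoint matrix
(neurons as observations) at the scree-curve knee, operationalised as the
component index maximising the discrete curvature
`r[i] − 2 r[i+1] + r[i+2]` of the explained-variance-ratio curve, with a
floor of 2 components and a "no clear knee" warning when the maximal
curvature falls below 0.01 (an isotropic-noise curve has curvature well
below this; a real knee sits well above it).

`cluster_ensembles()` is spectral clustering on the component scores: a
symmetric k-nearest-neighbour connectivity graph (default
`knn = round(sqrt(n))`), the symmetric normalized Laplacian, its k
smallest-eigenvalue eigenvectors row-normalized, then seeded k-means with
10 restarts. `k = 3` by default, mirroring the three reported ensembles;
the number was not derived from a model-selection rule in the source
workflow, so we keep it an explicit parameter. A graph with more connected
components than clusters errors with advice to raise `knn`.

`categorize_clusters()` names each cluster from data alone (never from
ground truth): the cluster-mean trial-averaged z over the 0–3 s
post-press segment is compared with ±0.5 z (configurable); above is
*excited*, below is *inhibited*, otherwise *non-responding*.

`tonic_bins()` implements the basal-fluorescence analysis: 3-min bin
means, normalized either per neuron to its first bin or to the
population-mean first bin — the published description admits both
readings, so both are implemented and the choice is a recorded argument.
Sessions vary in length, so the first-vs-last-bin contrast is the
session-level readout.

## Decoding

`build_epoch_features()` builds two balanced classes per session: the mean
fluorescence of each neuron in the 1 s immediately before every usable
press, and an equal number of random 1-s baseline epochs. Baseline epochs
are sampled without replacement, never overlap one another, and stay
outside `[−10, +13]` s around every press — the same extent as the
peri-event window — so baselines never touch modeled responses.

`decode()` is a linear-discriminant classifier with stratified 5-fold
cross-validation. Per-neuron decoding uses the exact closed form of
two-class, equal-prior, pooled-variance LDA in one dimension (classify to
the nearer class mean), vectorised over neurons; population decoding fits
LDA on the leading principal components of the training features (default
10), because epochs are far fewer than neurons and raw LDA would be
singular. A linear SVM is available behind a flag for comparison. LDA was
preferred as the default for its determinism and absence of
hyperparameters. When a training fold has zero within-class variance
(noiseless synthetic data), LDA degenerates gracefully to nearest
centroid.

`shuffle_null()` permutes class labels (never the time series) and re-runs
the decoder, 100 shuffles by default; `shuffle_subtracted_scores()`
subtracts from each neuron's accuracy the mean null accuracy of its group
(ensemble and/or session), matching how shuffle-referenced scores are
reported in this literature.

## Cross-session tracking

`match_rois()` matches cells across sessions by centroid position with a
Hungarian assignment on *gated* costs: distances beyond the 3-px threshold
all cost the same cap, and super-threshold pairs are dropped after
solving. The gating matters — an ungated global minimum will provably
sacrifice a genuine 1-px pair to shave distance off hopeless far pairs.
Shape ("structure") similarity is not used; the synthetic fixtures make it
unnecessary, and the hook for a shape term is the natural extension point.
`response_adaptation()` then compares matched cells' mean response z
across sessions, per ensemble, with a Pearson correlation as the
linear-association summary.

## Electrophysiology

The slice metrics operate on per-sweep peak amplitudes (peak detection
from raw sweeps is out of scope, keeping the module format-agnostic), with
inward currents negative, enforced at computation:

* `normalize_iv()` divides by |I(−80 mV)|.
* `rectification_index()` computes RI = I(+50) / −I(−70). An ohmic synapse
  reversing at 0 mV has RI = 5/7 exactly; calcium-permeable-AMPA-receptor
  synapses sit well below it. RI is a ratio, hence invariant to
  normalization — a property the tests exploit.
* `wash_effect()` contrasts the first and last 5 minutes of a drug-wash
  amplitude series.
* `spike_change_ratio()` normalizes post-wash evoked spiking to baseline.

## Statistics

The reporting layer wraps the standard machinery rather than re-deriving
it: `two_way_anova()` uses the classical sum-of-squares decomposition
(`aov`), with the repeated-measures variant blocking on subject (no
sphericity correction, matching how such designs are reported here);
`sidak_adjust()` is the closed form `1 − (1 − p)^m` applied to planned
contrasts (the contrast count is an explicit argument);
`chi_squared_test()` is Pearson's test without continuity correction;
`paired_t()` flags the zero-variance-difference case as a degenerate
infinite-t rather than erroring. Null calibration (uniform p-values under
simulated Gaussian data) is part of the acceptance suite.

## Numerical and scale choices

* All generators and all stochastic analysis steps are deterministic given
  their seed; seeds are ordinary integers below 2^31.
* Tests and the acceptance script simulate hour-long sessions at 10 Hz (or
  5 Hz where only slow structure matters) rather than the instrument's
  30 Hz — the window arithmetic is checked at 30 Hz separately, and the
  slower rate keeps the full pipeline simulation comfortably sized. The
  study-scale validation uses 305 neurons, ~40 press trials, amplitude
  ±0.5 dF/F and noise SD 0.2, with 20 independent seeds.
* The movie generator refuses overlapping ROIs, and tracked session pairs
  draw one joint non-overlapping centroid layout for the union of cells —
  distinct physical cells cannot occupy the same tissue position, and the
  planted cross-session correspondence is only well defined under that
  constraint.
* Degenerate inputs error loudly (empty ROI, no usable events, zero
  baseline, single-class decoding, zero-variance I–V normalization) rather
  than returning silent NAs.

## Known limitations

* Rigid, integer-pixel registration only; no non-rigid correction.
* No spike deconvolution or neuropil subtraction.
* Cell matching is positional; morphological similarity is not scored.
* The repeated-measures ANOVA is the subject-blocked decomposition; it is
  not a general mixed-model engine.
* Pipeline performance on real data depends on artifacts the synthetic
  generator deliberately omits (see above); the package validates
  correctness of the computations, not robustness to every imaging
  pathology.
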