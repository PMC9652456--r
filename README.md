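# ensembleseek

Analysis pipeline for deep-brain two-photon calcium imaging recorded during
head-fixed operant reward seeking, written for systems-neuroscience users
who need the full chain from ROI traces to ensemble statistics in R.

Thalamostriatal (PVT→NAc) projection neurons act as a tonic brake on reward
seeking: population activity drops around active lever presses, and the
population splits into excited, non-responding and inhibited ensembles with
distinct behavioral relevance. ensembleseek implements:

* **Operant schedule logic** — cue/sucrose delivery, 20-s timeouts, reward
  caps, extinction and reinstatement phase variants, plus the extinction
  criterion (≥10 days; 2 of the last 3 days ≤ 20% of late-acquisition
  pressing).
* **Imaging** — rigid integer-pixel registration by FFT cross-correlation,
  ROI mean-trace extraction, ΔF/F and first-bin normalization.
* **Ensemble detection** — peri-event tensors over the 23-s window
  (10 s pre, 3 s press-to-delivery, 10 s post), baseline z-scoring against
  the −10…−5 s segment, PCA with scree-knee component selection, spectral
  clustering (k-NN graph → normalized Laplacian → seeded k-means), and
  data-driven ensemble categorization at ±0.5 z.
* **Decoding** — per-neuron and population linear-discriminant decoding of
  a 1-s pre-press epoch vs random baseline epochs, stratified 5-fold CV,
  100-shuffle label-permutation nulls, and shuffle-subtracted scores
  `score_i = acc_i − mean(null acc of group(i))`.
* **Tonic activity** — 3-min bin means, first-vs-last-bin contrast of
  basal fluorescence (a proxy for tonic firing).
* **Cross-session tracking** — Hungarian centroid matching with a gated
  3-px threshold, response-adaptation contrasts and Pearson correlation
  across sessions.
* **Slice electrophysiology** — I–V normalization to the −80 mV peak, the
  AMPA rectification index RI = I(+50 mV)/−I(−70 mV) (ohmic reversal at
  0 mV gives RI = 5/7; calcium-permeable AMPA receptor synapses sit far
  below), first-vs-last-5-min drug-wash effects, evoked-spike ratios.
* **Statistics** — two-way (optionally subject-blocked) ANOVA with
  interaction, Sidak adjustment `1 − (1 − p)^m`, Pearson chi-squared on
  ensemble proportions, paired t-tests with degenerate-case handling.

A synthetic-data generator produces behavioral sessions, fluorescence
traces, movies with ROI masks, tracked session pairs and electrophysiology
series with planted ground truth, so the entire pipeline is testable
without any external data.

## Worked example

Simulate an hour-long self-administration session for a 305-neuron field
of view (79 excited / 153 non-responding / 73 inhibited), then run the
ensemble and decoding analyses:

```r
library(ensembleseek)

cfg    <- session_config(press_rate_active = 0.8, seed = 42)
events <- generate_events(cfg)
summarize_session(events)
#> $active_presses     [1] 57
#> $inactive_presses   [1] 10
#> $reinforced_presses [1] 41
#> $rewards_delivered  [1] 41

sim <- generate_traces(events, ensemble_spec_scaled(305),
                       frame_rate_hz = 10, seed = 42)
sim$traces
#> <trace_matrix> 305 neurons x 36000 frames @ 10 Hz

det <- detect_ensembles(sim$traces, events, k = 3, seed = 42)
table(det$category)
#>        excited      inhibited non_responding
#>             79             73            153

dec <- decode_session(sim$traces, events, grouping = det$category,
                      n_shuffles = 100, seed = 42)
round(tapply(dec$score, det$category, mean), 3)
#>        excited      inhibited non_responding
#>          0.479          0.486          0.024
round(mean(dec$null_accuracy), 3)
#> [1] 0.499

tonic <- tonic_bins(sim$traces)
round(mean(tonic$first_last$ratio), 3)
#> [1] 0.809
```

Reading the output: of 57 active presses, 41 were reinforced (the rest
fell inside timeouts). The pipeline recovers the planted three-ensemble
split exactly from the data and names the ensembles correctly. The excited
and inhibited ensembles decode upcoming presses ~0.48 above their shuffle
null while non-responders sit near zero, and the shuffle null itself is at
chance (0.5). The first-to-last 3-min-bin ratio of ~0.81 reflects the
default 20% within-session tonic decline sampled at bin centres.

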