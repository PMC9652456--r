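Package: ensembleseek
Title: Ensemble and Decoding Analysis of Deep-Brain Calcium Imaging During
    Reward Seeking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed operant reward seeking combined
    with deep-brain two-photon calcium imaging. Generates synthetic sessions
    with planted ground truth (operant event streams under a timeout/reward-cap
    schedule, fluorescence trace matrices with excited / non-responding /
    inhibited response ensembles and within-session tonic decline, movie
    stacks with ROI masks, cross-session tracked cell pairs, and slice
    electrophysiology I-V and drug-wash data); extracts and normalizes ROI
    traces from movies with rigid registration; builds peri-event tensors
    around active lever presses; selects principal components by scree-knee,
    spectrally clusters neurons into ensembles and categorizes them; decodes
    upcoming lever presses per neuron and at the population level against
    label-shuffle nulls; matches cells across sessions and quantifies response
    adaptation; computes AMPA rectification indices, drug-wash amplitude
    effects and evoked-spike changes; and provides the statistical layer
    (two-way ANOVA with Sidak post-hoc, chi-squared on ensemble proportions,
    paired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    igraph,
    stats,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
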