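---
title: "Analysing associative-memory coding in a compact neural network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing associative-memory coding in a compact neural network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormmem)
```

# Overview

`wormmem` implements an analysis pipeline for calcium-imaging and
behavioural data from *C. elegans* associative-learning experiments. The
experimental design crosses four training paradigms — short- and long-term,
each appetitive (with food) or aversive (starvation) — with trained,
mock-trained (treatment without the conditioned stimulus) and naive groups.
The conditioned stimulus (CS) is the odorant butanone (BUT); the alternative
attractant is diacetyl (DA). Recordings follow an exchange protocol: one
minute of DA, then six exchange trials of 30 s BUT followed by 30 s DA.
Sensory neurons are ON-type (respond to BUT onset) or OFF-type (respond to
BUT removal).

The pipeline covers: trace normalization and feature extraction; a pairwise
group-comparison design with positive-FDR adjustment; population decoding of
the training condition; a linear-combination model of interneuron activity;
PCA-based filtering of experience-component activity differences; locomotion
metrics from 2-D tracks; and an agent-based simulator of the two-choice
chemotaxis assay. Synthetic-data generators with planted ground truth make
every stage testable end to end.

# Trace processing

Raw fluorescence F is normalized by the neuron's ground state, F/F~G~. For
long exchange recordings the ground state is detected automatically: the
trace is smoothed by a centered 20-frame moving average (edges truncated),
and F~G~ is the mean of the smoothed values lying strictly below the 10%
quantile of the smoothed trace (linear-interpolation quantile on the sorted
values). If no value lies strictly below the quantile — a constant trace —
the quantile itself is used. For short recordings whose neuron returns to
baseline, F~G~ is the mean of the last 10 frames
(`detect_ground_state_tail()`). A visually identified ground state for
spontaneously active interneurons is supported as a manual `F_G` override in
`normalize_trace()`, not guessed. The alternative convention
(F − F~G~)/(F~max~ − F~G~) maps the ground state to 0 and the peak to 1; we
adopt this as the realization of peak-normalized fluorescence, which makes
the output invariant under affine transforms of the raw signal.

Mixed acquisition rates (2 Hz soma, 3–5 Hz neurite recordings) are
reconciled by linear interpolation to the highest frame rate in the dataset,
with no extrapolation beyond each trace's endpoints. Statistical summaries
integrate (sum) the normalized activity in a window of 10 s after each
stimulus switch; integration windows are exposed per neuron because response
kinetics differ among neurons. Decoding features bin each trace into
non-overlapping 20-frame bins (trailing partial bin dropped) and z-score the
bin means with the population-SD convention; a zero-variance vector maps to
zeros rather than NaN.

Choices the definitions leave open, fixed here once: the smoothing kernel is
*centered* with edge truncation (a trailing kernel shifts transients and has
no offsetting advantage); "below the quantile" is read *strictly*, with the
constant-trace fallback; bins are non-overlapping rather than rolling.

# Group statistics

The comparison design is an explicit 18-row table of pairwise group
contrasts (8 short-term rows, 10 long-term rows); the exchange dataset uses
the first 8. Each contrast carries an experience-component label: CS
(trained vs mock), US+ / US− (mock vs naive, appetitive/aversive), VAL
(appetitive vs aversive arm), TR (trained vs naive), SL (short vs long
term).

Before testing, summed activities are filtered per neuron × group to the
95% confidence band (mean ± 1.959964 SD). Normality is assessed per group by
Shapiro–Wilk below n = 50 and by Kolmogorov–Smirnov against a normal with
the sample mean and SD at or above it (the switch point is our choice; the
design only distinguishes "small" from "larger" samples). If both groups
look normal a t-test is used (paired where the design pairs observations),
otherwise the Wilcoxon rank-sum (unpaired) or signed-rank (paired) test.

Families of p-values are adjusted by Storey's positive false discovery rate
with the null proportion estimated at λ = 0.5; Benjamini–Hochberg is
available as a cross-check and, because it fixes π₀ = 1, always
upper-bounds the Storey q-values. Behavioural endpoints give the Choice
Index CI = (n~CS~ − n~alt~)/(n~CS~ + n~alt~) ∈ [−1, 1] and the Learning
Indices LI~stimulus~ = CI~trained~ − CI~mock~, LI~training~ = CI~trained~ −
CI~naive~, LI~treatment~ = CI~mock~ − CI~naive~, tested against zero by
one-sample t-tests with pFDR across the family.

Responder classification applies a neuron-specific threshold (a config
input; thresholds are data-dependent): a trial responds if the activity
crosses the threshold upward at least once; an animal responds if its six
consecutive trials contain at least two upward crossings. Only upward
crossings count — a downward crossing is the end of a response, not a
response.

# Synthetic data: what is emulated and what is not

`gen_trace_dataset()` builds raw-fluorescence traces over the exchange
schedule from a difference-of-exponentials transient kernel (1 s rise, 8 s
decay — GCaMP-like defaults; the recordings themselves do not constrain
kinetics), at stimulus onsets for ON neurons and removals for OFF neurons.
A planted neuron × experience-component effect matrix with columns
{US+, US−, CS(AP), CS(AV), VAL} sets each group's amplitude multiplier:
naive is the baseline; US columns act on the mock (and trained) groups of
their arm; CS columns act on trained groups relative to their mocks; VAL
shifts the two valence arms by ±VAL/2. Five groups span only four free
contrasts against naive, so VAL overlaps with the US contrasts; the ground
truth therefore records the *realized* per-group multipliers, from which the
expected value of any contrast is exact. Responder status is drawn per
animal or per trial (both modes exist because both kinds of variability are
analysed), supporting bimodal cohorts such as a neuron responding in only
~50% of animals. Noise is additive Gaussian (default SD 5% of the base
amplitude) over a slow sinusoidal baseline drift (≤ 5% amplitude, random
phase, 120 s period) — drifting baselines are evident in such recordings
but unmodelled, so the sinusoid is an artifact choice exposed in config.

Not emulated: biophysics, absolute fluorescence scales, photobleaching,
motion artifacts, or correlated noise across neurons. Consequently a
passing pipeline here demonstrates *procedural* correctness (contrasts,
filters, decoders and reconstructions recover what was planted), not that
real recordings satisfy the generator's assumptions.

One consequence of the feature transform matters when planting decoding
effects: binning + z-normalization removes each trial vector's offset and
scale, so a pure amplitude-gain effect is mathematically invisible to the
classifier features. Training-condition structure planted for decoding
therefore uses response-loss/gain barcodes (multipliers reaching 0 or 2) —
which is also the observed phenomenology, where specific neurons lose their
response entirely in specific training groups.

`gen_track_dataset()` plants per-group locomotion statistics directly at
the quantity the metrics measure: per 24-frame segment, a deviation angle
(truncated normal on [0, 180]°, random sign) rotates the direction to the
CS endpoint, a truncated-normal speed sets the step length, and Poisson
reversal events (per-cm rate) insert short backward excursions. Tracks are
absorbed at either endpoint, matching the assay in which arriving worms are
immobilized. The arena is a 10 × 6 cm rectangle with the start point 3.5 cm
from each endpoint, the assay geometry.

# Population decoding

Features concatenate, per animal and trial, each neuron's binned and
z-normalized trial segment. Three split schemes address three questions:
`trial` rows are (animal, trial) vectors; `within_individual` splits each
animal's six trials into halves, averaging each half into one vector per
animal per side; `between_individual` trial-averages per animal and splits
by animal, so no animal contributes to both sides. Splits are stratified
60/40 (stratification is our choice; only the ratio is fixed) and repeated
over 10 rounds; performance is the macro F1 score (unweighted mean of
per-class F1, zero-division → 0) with a row-normalized pooled confusion
matrix. Scrambled-label controls permute labels (at the animal level for
the grouped schemes) before splitting.

Three classifier backends: k-nearest-neighbours with k = 2 and
distance-weighted votes (we read the design's nearest-neighbour rule as
kNN with distance to the two nearest points), a 500-tree random forest, and
a multilayer perceptron with two hidden layers of 50 and 100 ReLU units
trained with Adam on the softmax cross-entropy (2000 full-batch iterations,
learning rate 10⁻³, small L2). The MLP is implemented in-package as a
minimal feed-forward network. No hyperparameter search is done anywhere.

# Linear-combination model of interneuron activity

For each training condition, neuron activities are averaged across animals
per trial within the 15 s window after the DA→BUT switch; the six averaged
vectors per neuron, concatenated, are the observations. The interneuron
(AIY in the motivating application) is fitted by ordinary least squares on
the sensory regressors with an intercept (activities are normalized but not
centered). Generalized least squares is deliberately not used — an
autoregressive GLS variant fits these data less accurately. The model is
fitted per condition, reporting coefficients with t-based p-values and
confidence intervals, R² and adjusted R². `incremental_fit()` adds
regressors in a stated order (R² is non-decreasing by nesting);
`crossval_fit()` guards against overfitting with a 50/50 split scored on
the held-out half; `within_animal_r2()` fits the simple one-regressor model
on simultaneously recorded pairs. Coefficients are reported unstandardized
and carry no synaptic-weight interpretation.

# Experience-component PCA filtering

Trial-averaged activities define six component contrasts per trial —
CS(AP) = STAP-T − STAP-M, CS(AV) = STAV-T − STAV-M, US+ = STAP-M − naive,
US− = STAV-M − naive, VAL(T) = STAP-T − STAV-T, VAL(M) = STAP-M − STAV-M —
giving a 36-row (component × trial) matrix whose columns are concatenated
per-neuron time points. PCA is taken over the 36 rows after column
centering (36 centered rows have rank at most 35, which fixes the
orientation); the reconstruction keeps a selected index set of components
(default {1, 2, 3, 5}) and adds the column means back so the deltas keep
their scale. Component selection is judgment exercised on the loadings, so
the package exposes the scores/loadings and variance report rather than
automating the choice. Retained and filtered variance fractions are
eigenvalue ratios and sum to one exactly; the Frobenius reconstruction
error equals the discarded eigenvalue mass.

Per neuron × component × trial, the reconstructed deltas are summed over
the neuron's time points and divided by the neuron's mean response
amplitude; the mean over the six trials gives the signed change and the SD
its spread. Whether amplitude should divide (amplitude-relative changes) or
multiply (amplitude-weighted changes) is genuinely ambiguous in the
original description; division is the default with a `weighting` switch.
Significance of change magnitudes uses 1-D k-means with k = 2 on the
absolute values: the larger-centroid cluster is significant, the boundary
is the centroid midpoint, and an all-equal input yields no significant
changes.

# Locomotion and the choice simulator

Tracks (center-of-mass positions) are analysed for their first 10 min and
segmented into non-overlapping 24-frame segments. The deviation angle is
the unsigned angle between the segment displacement vector and the
direction from the segment start to the target (0° toward, 180° away);
speed is polyline path length over duration (cm/min); distance to target
is taken at the segment midpoint. Reversals — any detectable backward
movement under center-of-mass tracking — are detected when the
instantaneous displacement projects negatively on the recent heading (a
trailing moving average over one segment) beyond a displacement threshold
(default 0.1 mm/frame); both knobs are config because "perceptible
backward movement" is qualitative. Rates are events per cm of path, binned
by distance to target (0.25 cm bins); profile summaries report the
proximal region 1.2–3.5 cm from the target.

The simulator draws each agent's speed and deviation angle per step from
the group's empirical distributions (conditioned on the agent's current
distance bin by default, since the measured profiles vary with distance;
sparse bins borrow from the pooled distribution), heads toward the CS
endpoint rotated by the drawn angle with random sign, and advances
speed × step. Reversal events arrive as a Poisson process at the per-cm
rate times the distance moved and turn that step backward. The step equals
one segment duration (8 s at 3 Hz), tying simulation resolution to
measurement resolution; both endpoints absorb (arriving worms are
immobilized in the assay); walls reflect. Absorption tests the closest
approach along each step so fast agents cannot step over an endpoint.
Hybrid cohorts take exactly one parameter from the trained group and the
rest from naive; the gap fraction of a parameter is the hybrid's share of
the naive-to-trained difference in final CS arrival fraction, with
Monte-Carlo intervals from replicate simulations.

# Numerical and testing notes

All randomness flows from explicit integer seeds; a fixed seed reproduces
datasets, splits, simulations and fits bit for bit. Numeric primitives
(moving average, quantile, ground state, window integration, macro F1, OLS,
1-D k-means) are tested against independently coded brute-force oracles on
a thousand random small instances at 10⁻⁸. The test suite's problem sizes
are chosen to exercise the statistics at desk scale: the null-FDR check
uses 204 hypotheses × 100 replicate datasets; decoding uses 8 neurons ×
5 groups × 15 animals × 6 trials; the simulator checks use cohorts of up to
2000 agents. Known limitations: the comparison machinery assumes the
closed label set; the generator's Gaussian noise understates heavy-tailed
imaging artifacts; the simulator has no odor-gradient model and no
agent–agent interactions, so only relative (hybrid vs naive vs trained)
arrival statistics are meaningful.
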