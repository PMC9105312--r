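---
title: "Detecting focal onset motor seizures from wrist-worn biosignals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting focal onset motor seizures from wrist-worn biosignals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Focal onset motor seizures — seizures arising from a single brain region with
tonic (sustained contraction) or clonic (rhythmic jerking) movements, without
bilateral spread — are weakly and inconsistently expressed in the biosignals a
wrist wearable can measure. A detector must find rare events of 10 s to 10
minutes inside days of recording dominated by ordinary movement, against
autonomic responses (electrodermal surges, tachycardia) that some seizures
and some patients simply do not produce. `ictalwear` implements the full
chain for this problem: multimodal feature extraction on a 2-s grid, a
cost-weighted boosted tree detector, event-based scoring, and the two
evaluation designs that matter clinically — personalized (intra-subject) and
population (inter-subject) cross-validation.

## Data model

A recording is a list of **contiguous segments**; each segment holds one
channel per modality (ACC 32 Hz in g, EDA 4 Hz in µS, BVP 64 Hz in arbitrary
units, optionally skin temperature) sharing a start epoch. Wearables stream
over Bluetooth and swap devices for charging, so gaps are first-class: no
value is ever imputed across a gap, feature windows touching a gap are
masked, and the recorded-hours denominator of false alarm rates excludes
gaps. On disk, a segment is a directory of per-channel CSVs (line 1 epoch
start, line 2 sample rate, then samples; ACC stored in the device's 1/64-g
counts) with a JSON sidecar for participant id, wrist, and the local-time
offset needed for nightly false alarm accounting.

Annotations carry onset/offset epoch seconds plus semiology metadata (motor
flags, tachycardia, vigilance, device-vs-seizure laterality). Annotation
intervals are treated as **closed** `[onset, offset]` and grid intervals as
half-open `[t, t+2)`: a grid interval is ictal when the two overlap. The
peri-ictal training spans `[onset − 600, offset + 600]` use the same closed
convention, so with zero padding the training rows are exactly the
ictal-labeled rows.

## Features

Eleven features per 2-s grid point. Masked (invalid) entries are `NA`
throughout and only imputed at the model boundary.

**Accelerometry — recurrence quantification** over the 10-s window centered
at the grid point. The raw 3-axis samples are the phase-space trajectory (no
time-delay embedding: three axes already give a 3-D state; an embedding of
the magnitude signal was considered and rejected as an extra free parameter
with no stated values to anchor it). The recurrence plot thresholds pairwise
Euclidean distances at a radius, by default 10% of the window's maximum
pairwise distance — an adaptive choice that keeps the recurrence rate
comparable between quiet sleep and vigorous movement; a fixed radius is
available (`fixed_radius`). The line of identity is excluded: the recurrence
rate has denominator N² − N, so a constant window scores exactly RR = 1.
Four measures are emitted: RR, determinism (points on diagonals of length
≥ `l_min` = 2 samples, the usual convention, over all recurrent points),
average diagonal line length (NA sentinel when no line reaches `l_min`), and
the Shannon entropy of the diagonal-length distribution (0 in degenerate
windows). The O(N²) distance-and-diagonal scan runs in C++ (N = 320 per
window, one window per 2 s of recording).

**Electrodermal activity.** The skin conductance level is a 60-s centered
moving mean, implemented as the classic even-order (240-sample) centered
average with half-weight end samples — the discrete form that maps a linear
ramp to itself and a unit impulse to an interior plateau of exactly 1/240.
Each feature differences a trailing 5-min feature window `[t − 300, t]`
against the preceding baseline window `[t − 600, t − 300]`: ΔAUC
(trapezoidal), Δmax, and ΔSCRR, where SCRR counts upward crossings of
+0.01 µS/s by the first derivative of the smoothed signal. Upward-only
counting and the 0.01 µS/s threshold separate discrete skin-conductance
responses from drift at 4 Hz; both are configurable. Differencing makes all
three features exactly invariant to the tonic level. The baseline-precedes-
feature orientation is deliberate: the alternative ordering (baseline after
the feature window) would be anti-causal at detection time; it remains
available behind `baseline_after = TRUE` for sensitivity analyses. Grid
points less than one full baseline span (600 s, plus one grid step so the
first trapezoid exists) into a segment are masked.

**Blood volume pulse.** Beats are local minima of the raw waveform — the BVP
dips at systolic inflow — gated by depth relative to a rolling peak-to-peak
amplitude and a 0.33-s refractory period (≤ 180 bpm). The heart-rate estimate
applies, in order: an IBI plausibility range of 0.33–2 s (30–180 bpm), a
±25% gate against the running 5-beat median, a 5-beat median filter, linear
interpolation to the grid, and a 10-s validity horizon around retained
beats. These cascade constants are package defaults, all exposed as
arguments: the principle (plausibility, outlier gate, smoothing, validity
horizon) matters more than any one value, and every value is testable. The
quality index is the normalized Shannon entropy of the single-window
periodogram restricted to 0.5–5 Hz: near 0 for a clean pulse (one dominant
line), near its flat-spectrum expectation (≈ 0.89 for the 46 in-band bins of
a 10-s window; exactly 1 is unreachable for a finite periodogram) for
broadband artifact, and 1 by convention for an all-zero window, which
carries no quality evidence. No Welch or Daniell smoothing is applied:
averaging would spread a pure tone across bins and destroy the near-zero
contract for clean pulses. The differenced HR features (Δmax, Δmean over
60-s windows against the prior 60 s) are masked when more than half of
either window lacks valid HR; the SQI and HR point features keep their own
validity, since artifact is itself information.

## Detector

AdaBoost.M1 over depth-limited CART weak learners (`rpart`, Gini splits,
`cp = 0`, no surrogates). The false-positive misclassification cost enters as
initial observation weights — non-seizure rows weighted `fp_cost`, seizure
rows 1 — so a background row misclassified as ictal costs `fp_cost` times as
much in every round's weighted error; the false-negative cost is never
tuned. Each round's vote is `alpha = learning_rate · ½ log((1 − err)/err)`;
boosting stops early on a perfect round or one no better than chance.
Training is deterministic given the data, so fixed seeds give bit-identical
models.

Masked feature values are imputed at the training mean (0 after z-scoring) —
the least informative finite value for a tree — with no added is-valid
indicator columns, keeping the feature count at exactly 11. Normalization
parameters (per-feature mean and standard deviation) are fitted on training
rows only, stored in the model bundle, and applied unchanged to test data;
constant training features are a hard error.

Hyperparameter search is a grid over learning rate, ensemble size, tree
depth, and FP cost, scored at the event level per cross-validation fold and
averaged (the flat design: one optimization over all folds per combination).
Selection order: highest mean sensitivity, lowest mean FP count, then —
breaking ties toward cheaper models — higher learning rate, fewer learners,
and finally shallower depth and lower cost so the order is total and the
winner unique. The default grid is 5 × 4 × 5 × 6 = 600 combinations
(`param_grid_default()`); the harnesses default to a 24-combination desk-
scale preset (`param_grid_reduced()`: learning rate {0.1, 0.5}, learners
{20, 50}, depth {1, 2}, FP cost {1, 5, 20}) chosen once to span the four
axes at the smallest useful cardinality.

Feature importance is the total Gini impurity decrease per feature, averaged
over the ensemble's trees (and over per-fold models in the intra-subject
design), floored at 0 — unused features score exactly 0.

## Event scoring

Grid predictions are smoothed per contiguous chunk — gaps of at most 30 s
between seizure labels are filled first, then orphan runs shorter than 6 s
(the event minimum, the natural reading of "orphan") are removed; the order
matters and is fill-then-remove. Maximal runs of 6 s–10 min become events;
runs longer than 10 min are truncated to their first 600 s and counted once
(splitting them would mint arbitrarily many false alarms from one excursion).
Truth events are extended by a 2-min margin on both sides; any overlapping
prediction makes the truth event one true positive, absorbing all
predictions that overlap it; unmatched predictions are false positives and
true negatives are never counted. FAR24 = FP × 24 / recorded hours.
FARn = night FPs × 8 / nightly hours recorded, where a FP is nightly if its
*start* (the alarm moment) falls in 23:00–07:00 local time and the
denominator counts only recorded data overlapping night windows. Both
pooled (total counts) and mean-of-fold aggregations are reported — they
differ, and each answers a different question.

## Cross-validation designs

**Intra-subject (leave-one-seizure-out)**, for participants with ≥ 3
retained seizures: each fold trains on the ±10-min peri-ictal rows of the
other seizures and tests on the complete remaining recording — including the
left-out seizure, excluding every training row and a further 600-s guard
band around the training spans, so no test feature window shares raw data
with a training row. Train/test index disjointness is asserted on every
fold.

**Inter-subject (leave-one-participant-out)**: grid search over the training
cohort, validating each combination on each held-out training participant's
complete recording; the winning parameters train one final model on all
training-cohort peri-ictal data, which is then applied to every test-cohort
participant's full recording. Cohort overlap is an error.

## The synthetic cohort generator

The generator emulates exactly the structure the features respond to:
circadian accelerometry (quiet nights, bout-structured daytime movement from
a two-state Markov envelope), EDA tonic drift plus Poisson spontaneous
skin-conductance responses (about 1/min awake, 1/5 min asleep, 0.2–1 µS),
a pulsatile BVP waveform with slowly wandering heart rate and broadband
artifact coupled to the movement envelope (so the quality index degrades
whenever the wrist moves, ictally or not), and device-swap gaps. Ictal
overlays per seizure: tonic — sustained 0.4-g posture offset with 8–12 Hz
low-amplitude tremor; clonic — 2–5 Hz rhythmic bursts; responders — a
0.5–3 µS conductance response rising within 0–20 s of onset and decaying
over minutes; tachycardia — a +20–50 bpm ramp from onset decaying after
offset. A contralateral device attenuates ictal ACC by 0.25×. A global
`effect_scale` multiplies every ictal effect; 0 yields null data for
negative controls. All randomness flows from one master seed through
deterministic per-participant sub-seeds.

The default cohort preset has nine participants and 20 seizures — three
multi-seizure participants (6, 3, 3) for the intra-subject/training side and
six test participants with one or two seizures each — with 24–28 h of
recording per participant: the smallest scale that passes the ≥ 24-h
inclusion filter while keeping a full evaluation around seven minutes on one
CPU. Recordings of tens of hours per participant would change nothing
structurally. Seizure durations are drawn U(30, 150) s, comfortably inside
the 10 s–10 min inclusion bounds; the tonic/awake participant has one
non-responder seizure (a phenotype that occurs clinically and stresses the
EDA features). All default profiles wear the device on the seizure side:
the preset is a *positive control*, in which every modality carries its full
ictal effect, and its expected behavior — per-participant sensitivity 1.0
with FAR24 below 2, out-of-sample pooled sensitivity ≥ 0.8 — is asserted in
the acceptance tests. An earlier draft of the preset gave one training
participant a contralateral device; that configuration is still a one-line
profile change, and it degrades the false-alarm rate by an order of
magnitude (the model, deprived of movement evidence, leans on electrodermal
features and fires on spontaneous SCR clusters) — a faithful illustration of
why laterality matters clinically, but not a control condition.

What the generator does **not** model: EEG, real semiological variability
within a seizure, age- or syndrome-specific physiology, posture, skin
temperature dynamics, sensor drift, or realistic artifact spectra. Passing
the positive control therefore shows the pipeline is correct and sensitive
under its own assumptions — not that any particular clinical performance
would be achieved on patient data.

## Data selection

The inclusion filters are explicit and logged: recordings need ≥ 24 h of
data; seizures need durations of 10 s–10 min (inclusive). The visual
screen for unusable peri-ictal EDA is operationalized as two numeric
heuristics — a flat-zero flag (≥ 50% of peri-ictal samples below 0.01 µS:
electrode contact loss) and an instability flag (more than ten 2-s epochs
with |ΔEDA| above 5 µS/s: loose device). These thresholds approximate a
judgment call and are configurable; the flags are reported rather than
enforced. Seizures are deliberately *not* filtered by device-vs-seizure
laterality.

## Numerical choices and degenerate inputs

- Empty or single-class training labels, overlapping cohorts, too few
  seizures, zero-variance features, and zero recording hours are hard
  errors naming the violated rule.
- Degenerate recurrence windows (no recurrent points / no lines ≥ `l_min`)
  return RR = 0, DET = 0, ENTR = 0 and an NA length sentinel.
- An all-masked grid row is predicted non-ictal; an all-zero BVP window has
  SQI 1.
- Flat BVP yields an empty beat series and an all-invalid HR estimate.
- The event matcher classifies every prediction exactly once (absorbed by a
  truth event or counted as one FP), so TP + FN equals the number of truth
  events on any input.

## Problem sizes

The test suite and the acceptance script run the full default cohort
(9 × ~26 h, ≈ 425,000 grid points cohort-wide) with the 24-combination grid:
about 6–7 minutes each on a single CPU, dominated by per-fold grid-search
training and whole-recording prediction. Unit tests use minutes-long
fixtures. These sizes are the package's chosen desk scale; every stage
accepts larger inputs unchanged.

## Known limitations

- The recurrence-analysis configuration (no embedding, adaptive 10% radius,
  `l_min` = 2) is one reasonable point in a family of conventions; with the
  adaptive radius, a perfectly still wrist with white sensor noise scores
  *low* determinism (the radius shrinks to the noise scale), so "stillness"
  is recognizable only through slow postural drift. The fixed-radius option
  changes this behavior.
- The HR filter cascade constants are defaults, not canon; PPG beat
  detection on real data is harder than on the synthetic pulse shape.
- The EDA quality heuristics stand in for expert visual review.
- Event-level scoring carries no detection-latency notion: a prediction 90 s
  after offset (within the margin) counts the same as one at onset.
- Intra-subject grid search is flat (scores averaged over folds per
  combination); a fully nested design would cost folds × combinations more
  compute and is not implemented.
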