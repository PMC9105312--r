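# ictalwear

Detection of focal onset motor seizures from wrist-worn wearable biosignals.

Focal onset seizures with tonic (sustained contraction) or clonic (rhythmic
jerking) motor signs are far harder to detect from a wrist wearable than
generalized convulsive seizures: the movements are weaker, the autonomic
responses inconsistent, and the signals heavily corrupted by everyday
activity. `ictalwear` implements a complete, tested pipeline for this
problem, for researchers who work with Empatica-E4-style recordings (3-axis
accelerometry at 32 Hz, electrodermal activity at 4 Hz, blood volume pulse at
64 Hz) and expert seizure annotations, and for anyone who wants a fully
synthetic test bed for event-based seizure-detection methodology.

## What it computes

**Features** on a uniform 2-s grid, 11 per grid point:

- *Accelerometry — recurrence quantification.* For each 10-s window the
  3-axis samples are treated as a trajectory in R³; the recurrence plot
  thresholds pairwise distances at radius ε (by default 10% of the window's
  maximum distance), and four measures summarize its diagonal structure:
  recurrence rate `RR = #{(i,j): i≠j, d_ij ≤ ε} / (N² − N)`, determinism
  `DET` (fraction of recurrent points on diagonals of length ≥ l_min = 2),
  average diagonal line length `L`, and the Shannon entropy
  `ENTR = −Σ p(l) ln p(l)` of the diagonal length distribution. Rhythmic
  clonic movement produces long diagonals; unstructured movement does not.
- *Electrodermal activity.* Skin conductance level (SCL) = 60-s centered
  moving mean; each feature is the value over the trailing 5-min window minus
  the same value over the 5 minutes before it: ΔAUC(SCL), Δmax(SCL), and
  ΔSCRR, the difference in counts of upward derivative-threshold crossings
  (0.01 µS/s) — isolating peri-ictal electrodermal responses from tonic
  drift.
- *Blood volume pulse.* Trough-based beat detection with a refractory period
  and plausibility/median filters yields a heart-rate estimate on the grid;
  features are Δmax(HR) and Δmean(HR) over 60-s windows against the prior
  60 s, the HR itself, and a spectral-entropy signal quality index
  `SQI = −Σ p_k ln p_k / ln K` over the 0.5–5 Hz periodogram — motion
  artifact is treated as information, not discarded.

**Detector.** AdaBoost.M1 over depth-limited CART trees with an asymmetric
misclassification cost: non-seizure rows carry weight `fp_cost ≥ 1` so false
alarms are penalized; false negatives stay unweighted. Hyperparameters
(learning rate, ensemble size, tree depth, FP cost) are grid-searched with
event-level scoring; ties break toward higher learning rate and fewer trees.

**Scoring.** Predictions are smoothed (gaps ≤ 30 s filled, runs < 6 s
removed), turned into events of 6 s–10 min, and matched to annotated seizures
with a 2-min margin. Reported: sensitivity `TP/(TP+FN)`, positive predictive
value `TP/(TP+FP)`, false alarm rate per 24 recorded hours
`FAR24 = FP · 24 / hours`, and per standard night
`FARn = FP_night · 8 / nightly hours recorded` (23:00–07:00 local).

**Evaluation harnesses.** Intra-subject leave-one-seizure-out (train on the
±10-min peri-ictal data of the other seizures, test on the full remaining
recording) and inter-subject leave-one-participant-out with a held-out test
cohort. Z-score normalization is fitted on training rows only and applied,
stored, to test data.

**Synthetic cohorts.** `generate_cohort()` builds multimodal recordings with
circadian activity, spontaneous skin-conductance responses, pulsatile BVP
with movement-coupled artifact, device-swap gaps, and planted seizures
(tonic/clonic/mixed, optional EDA response and tachycardia, contralateral
attenuation) — so the whole pipeline is testable without clinical data.

## Worked example

```r
library(ictalwear)

gp <- generate_participant(synthetic_profile("P01"), total_hours = 6,
                           n_seizures = 4, seed = 7)
pd <- prepare_participant(gp$recording, gp$annotations)
pd
#> <participant_dataset P01: 6.0 h, 10800 grid rows, 4/4 seizures retained>

res <- run_intra_subject(pd, grid = param_grid_reduced())
res$best$fp_cost
#> [1] 20
res$fold_reports[[1]]
#> <score_report: TP 1, FP 0, FN 0 | sensitivity 1.00, FAR24 0.00, PPV 1.000>
res$aggregate$pooled_sensitivity
#> [1] 1
res$aggregate$mean_far24
#> [1] 0
round(sort(res$importance, decreasing = TRUE)[1:4], 4)
#>  f_bvp_sqi f_acc_entr  f_acc_det   f_bvp_hr
#>     0.0113     0.0083     0.0048     0.0022
```

Each fold trains on the peri-ictal data of three seizures and scans the
remaining six hours for the left-out one: all four are recovered
(sensitivity 1.0) with no false alarms (FAR24 = 0), and the winning
configuration uses the highest false-positive cost in the grid. The Gini
importances show which feature streams the per-participant model actually
used — here the BVP quality index and the accelerometry recurrence measures.

The same pipeline runs from the shell via the thin CLI:

```sh
Rscript inst/cli/ictalwear simulate config.json
Rscript inst/cli/ictalwear features config.json
Rscript inst/cli/ictalwear evaluate config.json
```

with a validated JSON/YAML config (see `?cmd_simulate`).

## Package layout

- `R/channels.R`, `R/session_io.R` — domain types; session/annotation CSV I/O
- `R/rqa.R` + `src/rqa.cpp` — recurrence quantification (C++ inner loop)
- `R/eda.R`, `R/bvp.R` — electrodermal and pulse features
- `R/dataset.R` — feature grid, labels, peri-ictal extraction, z-scoring,
  selection filters
- `R/detector.R` — cost-weighted AdaBoost, grid search, Gini importance
- `R/scoring.R` — smoothing, events, margin matching, FAR24/FARn/PPV
- `R/harness.R` — intra-/inter-subject cross-validation
- `R/synthetic.R` — cohort generator
- `R/cli.R`, `inst/cli/ictalwear` — config-driven pipeline commands
- `vignettes/methods.Rmd` — the methods vignette (model, parameters,
  assumptions, limitations)
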