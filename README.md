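# neurotrait

Resting-state EEG **neural traits** of risk-taking and strategic consistency:
a tested R implementation of the full analysis chain linking personality,
task-independent brain activity, and risky decision-making.

## The scientific problem

Individual differences in risk-taking are large but poorly explained —
personality self-reports predict risky behaviour only weakly. The
neural-trait approach interposes stable, task-independent brain measures:
resting-state current-density maps (per frequency band, per voxel) are
regressed on behaviour, and personality is allowed to act on behaviour
*through* the identified neural traits. This package is for researchers who
want that chain as reusable, unit-tested components rather than a one-off
script pile: behavioural scoring, spectral feature extraction, whole-map
permutation statistics, variance partitioning, and bootstrap mediation.

## What it computes

* **BART scores** — risk-taking `RT = mean(pumps) · (explosions + 1) / n_trials`
  (all trials, explosions included) and the coefficient of variability
  `COV = sd(pumps) / mean(pumps)`, an inverse index of strategic consistency.
* **Band power** — 2-s Hamming-windowed epochs, 75 % overlap, seven bands
  (delta 1.5–6 Hz … beta3 21.5–30 Hz), artifact rejection
  (±100 µV, 50 µV step, 0.5 µV/100 ms low-activity), total-density
  normalization + log transform, split-half reliability via Cronbach's α.
* **Whole-map correlation with FWER correction** — per-voxel Pearson r
  against a behavioural score; the corrected threshold is the 95th
  percentile of the permutation distribution of the maximum |r| over all
  voxels; corrected p = (1 + #{null max ≥ |r|}) / (B + 1). Contiguous
  supra-threshold clusters (6/18/26-connectivity) and 10-mm sphere ROIs.
* **Commonality analysis** — exact partition of the two-predictor regression
  R² into variance unique to RT, unique to COV, and shared.
* **Mediation (model 4)** — OLS paths a, b, c, c′ with indirect effect a·b
  and percentile-bootstrap CIs (10,000 case resamples), unstandardized and
  standardized.
* **Synthetic cohorts** — 20-trial BART sessions (thresholds uniform on
  [2, 28], mean 15), trait tables, and spatially smooth voxel maps with
  planted effect clusters and a personality → neural → behaviour chain, so
  the whole pipeline is testable with no download.

## Worked example: the analysis workflow

The `analysis/` directory holds the numbered workflow; each script reads the
previous stage's outputs from `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort with two planted clusters
Rscript analysis/02_score_bart.R        # RT / COV per subject
Rscript analysis/03_voxelwise_mapping.R # permutation-corrected maps + clusters
Rscript analysis/04_roi_commonality.R   # sphere ROIs, correlations, commonality
Rscript analysis/05_mediation.R         # personality -> ROI -> behaviour
Rscript analysis/06_spectral_reliability.R
```

Stage 2 prints the cohort's behavioural summary (104 simulated subjects):

```
  measure      mean        sd        min       max
1      rt 4.1096154 2.9791671 0.17750000 14.582500
2     cov 0.4587176 0.1887556 0.08391559  1.042938
```

— heterogeneity at the scale reported for real cohorts (RT mean ≈ 3.9,
SD ≈ 2.7). Stage 3 detects both planted delta-band clusters and nothing
else; the corrected |r| threshold over the 1,728-voxel map is ≈ 0.35:

```
  score_name size peak_x_mm peak_y_mm peak_z_mm    peak_r    mean_r corrected_p
1         rt   33        25        35        45 0.5912108 0.5743483       5e-04
2        cov   33        45        40        45 0.5662620 0.5518333       5e-04
```

Stage 4 shows the point of the commonality step — each neural trait's
explained variance is attributed overwhelmingly to *its* behavioural score
(91.9 % unique to RT for the risk-linked ROI; 96.7 % unique to COV for the
variability-linked ROI). Stage 5 recovers the planted mediation chain:

```
             x             m   y indirect     se  ci_low ci_high
  extraversion  roi_rt_delta  rt   0.5983 0.2632  0.1447  1.1814
      openness roi_cov_delta cov   0.1101 0.0260  0.0648  0.1667
```

The planted driving traits (extraversion for RT, openness for COV) show
indirect effects whose 95 % bootstrap CIs exclude zero. (With twelve
uncorrected exploratory models an occasional spurious interval is expected —
this run also flags one weak conscientiousness → COV path.)

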