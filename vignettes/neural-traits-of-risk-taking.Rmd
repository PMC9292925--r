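---
title: "Methods: resting-EEG neural traits of risk-taking and strategic consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-EEG neural traits of risk-taking and strategic consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotrait)
```

## The analysis in one paragraph

People differ widely in how much risk they take and in how consistently they
pursue a strategy while doing so. The neural-trait approach asks whether
stable, task-independent features of resting brain activity explain that
heterogeneity. This package implements the full statistical chain of such a
study: behavioural scoring of the Balloon Analogue Risk Task (BART),
band-power extraction from cleaned resting EEG, mass-univariate correlation
of per-voxel current-density maps with behaviour under max-statistic
permutation correction, contiguous-cluster and sphere-ROI extraction,
commonality partitioning of the variance two behavioural predictors explain
in a neural trait, and single-mediator bootstrap models of a personality →
neural trait → behaviour chain. A synthetic-cohort generator with planted
effects makes every stage testable without any data download.

## Behavioural measures

Each subject inflates 20 balloons with hidden explosion thresholds
(integer-uniform, support 2–28 pumps, mean 15). Two statistics summarize a
session:

* **Risk-taking (RT)** = mean pumps over *all* trials × (explosions + 1) ÷
  number of trials. Exploded trials contribute their recorded pumps: an
  explosion is itself a risky outcome, and a measure restricted to safe
  trials would understate risk appetite. This convention is also the only
  one compatible with cohort RT means near 4 at plausible pumping rates.
* **Coefficient of variability (COV)** = SD(pumps) ÷ mean(pumps), an
  *inverse* index of strategic consistency: a subject adjusting pumping in
  small steps (8 → 9 → 10 → 11) scores ≈ 0.14, an erratic one
  (5 → 15 → 2 → 18) ≈ 0.77. The sample (n−1) SD is the default; the
  population-SD variant is available (`sd_type = "population"`) because the
  convention is not universal in the COV literature.

RT rank-correlates above 0.9 with the simpler total-pumps and average-pumps
indices on default synthetic cohorts, so conclusions do not hinge on the
specific formula.

## Spectral stage

The cleaning contract assumes ocular artifacts were removed upstream. The
package then re-references to the mastoid average, resamples to 256 Hz,
band-pass filters 0.1–30 Hz with a 60-Hz notch (zero-phase Butterworth via
forward–backward filtering; the filter family and order are arguments, since
only the cutoffs are scientifically constrained), and keeps eyes-closed
segments. Artifact-contaminated 2-s epochs are rejected by three rules
applied per channel: amplitude outside ±100 µV, an adjacent-sample step
above 50 µV (the "per adjacent sample pair" reading of a maximum-voltage-step
criterion; the window is configurable), and a low-activity rule flagging any
100-ms interval with range below 0.5 µV.

Band power uses Hamming-windowed periodograms of 2-s epochs overlapping by
75%. At 2-s epochs the frequency resolution is exactly 0.5 Hz, and the seven
canonical bands (delta 1.5–6, theta 6.5–8, alpha1 8.5–10, alpha2 10.5–12,
beta1 12.5–18, beta2 18.5–21, beta3 21.5–30 Hz) have half-integer edges, so
assigning a bin to a band iff its centre lies in `[low, high]` inclusive is
exact and gap-free. Within a band the member-bin powers are **averaged**
(with `aggregate = "sum"` available): the averaged reading matches the
"average power per band" convention, while the summed reading makes
band power proportional to bandwidth on white noise; both are tested. No
window amplitude correction is applied — every downstream statistic compares
subjects, not absolute power. The periodogram is scaled so total power
equals windowed time-domain energy (Parseval), which the tests verify to
1e-6 relative error.

Current-density-style maps are normalized per subject and band to total
density 1 and log-transformed (`normalize_log_map()`), which removes overall
scale exactly. Split-half reliability (four 30-s segments, each epoched,
cleaned and spectral-analysed independently) is summarized by Cronbach's
alpha across subjects; stationary synthetic signals exceed 0.9, mirroring
the internal-consistency demonstration expected of trait-like measures.

## Mapping stage

`voxelwise_correlation()` computes the Pearson correlation of each voxel
with a behavioural score — identical to the standardized slope of the
per-voxel simple regression. Family-wise error over the whole map is
controlled by max-statistic randomization: subject labels of the score are
permuted, the maximum |r| over voxels recorded per permutation, the
corrected threshold taken as the empirical 95th percentile (type-1,
inverse-CDF quantile, so ties resolve conservatively), and each voxel's
corrected p computed as `(1 + #{null max ≥ |r|}) / (B + 1)`, which includes
the observed statistic and so never returns zero. Choices made where the
field's practice varies:

* **Two-sided** max-|r| null — sidedness is rarely stated in published maps;
  two-sided is the conservative default.
* Correction is **within band and score**, matching an analysis run
  separately per frequency band; an omnibus correction across bands/scores
  would be stricter and can be emulated by pooling maps before calling the
  function.
* Cluster connectivity defaults to **26-neighbour** ("contiguous" in the
  loosest lattice sense), with 6 and 18 available; clusters are
  sign-homogeneous, and both the peak r and the cluster mean r are reported
  (plus the minimum |r|, since "cluster-level r" conventions differ).
* Sphere ROIs use inclusive Euclidean distance; on a full 5-mm lattice a
  10-mm sphere centred on a voxel contains exactly 33 voxels.

## Synthetic cohorts: what is emulated, and what is not

`simulate_cohort()` generates the joint structure every downstream stage
assumes, with defaults frozen at the study conditions:

* 20-trial sessions, thresholds integer-uniform on [2, 28]. Only the mean
  (15) of the threshold distribution is scientifically fixed; the uniform
  family is an assumption, surfaced in the configuration, chosen because it
  is simple, mean-correct and bounded away from trivial thresholds. Subjects
  draw independent sequences by default (`shared_thresholds` yokes them).
* Pumping behaviour: intended pumps per trial are rounded Gaussians
  (floor 1) with subject-level mean `mu` and SD `sigma` — two interpretable
  knobs mapping onto RT and COV. The `"adaptive"` policy raises the mean by
  1 after each safe trial and lowers it by 1 after an explosion, emulating
  small-step strategy; `"iid"` keeps it fixed. Recorded pumps cap at the
  threshold and the balloon explodes iff intended pumps reach it.
* The causal chain: standardized personality latents (reported on a
  Likert-like 1–5 scale as 3 + 0.6z, clipped); per planted cluster a neural
  latent `a·z_trait + sqrt(1−a²)·e` (unit variance); behavioural latents
  `b·z_latent + sqrt(1−b²)·e`, so `b` *is* the planted behavioural–neural
  correlation; and the affine, clipped maps `mu = 11 + 5·risk` (range
  [2, 25]) and `sigma = 3 + 1·variability` (range [0.5, 8]). The 11/5 and
  3/1 constants were calibrated once against the published cohort
  descriptives (RT mean ≈ 3.9, SD ≈ 2.7; COV mean ≈ 0.47, SD ≈ 0.13) and
  then frozen; default cohorts land near those values.
* Voxel maps: planted voxels carry the cluster latent plus per-voxel noise;
  background voxels carry Gaussian noise smoothed with a 30-mm-FWHM kernel.
  Source-localized EEG maps are intrinsically smooth (the inverse solution
  has centimetre-scale resolution), and smoothness determines the effective
  multiplicity the max-statistic correction faces. The default FWHM was
  chosen so the corrected |r| threshold at n = 104 on a 1,000-voxel lattice
  (≈ 0.33) is consistent with published whole-map thresholds in this
  paradigm, where peak correlations near 0.35 survive correction over ~6,000
  voxels. Background fields are given zero spatial mean per subject, so the
  total-density normalization adds no subject-level offset — without this
  the normalization visibly attenuates planted correlations. Raw values are
  exponentiated (log-normal densities) and passed through
  `normalize_log_map()`, making post-normalization values Gaussian-like, as
  the linear models downstream assume.

Limitations a user should know. The BART model has no learning or
optimal-stopping psychology beyond the adaptive step rule, and no payoff
accounting. Measured COV picks up threshold-truncation variance, so
synthetic RT and COV correlate slightly *negatively* (≈ −0.2) where real
cohorts report a weak positive association; conclusions about the
mapping/commonality/mediation machinery are unaffected because those operate
on whatever scores they are given. Raw-EEG synthesis is limited to
sinusoid-plus-noise fixtures — the spectral stage is validated on signals
with known spectra, not realistic EEG morphology. The source-localization
inverse itself (and any atlas labelling) is out of scope: the pipeline
consumes voxel-space maps, and peak coordinates are reported numerically.

## Commonality and mediation

For two predictors, the regression R² of `y ~ x1 + x2` (OLS with intercept,
the standard commonality-analysis definition) decomposes exactly into
`unique_x1 = R²_full − R²_x2`, `unique_x2 = R²_full − R²_x1`, and
`common = R²_x1 + R²_x2 − R²_full`; the identity holds to machine precision
and is exercised property-style on random data. Negative common variance
(suppression) is reported, never clipped. Percentages are components over
the full R², which is why they sum to 100 whenever R² > 0.

Mediation follows the single-mediator ("model 4") computation: `a` from
`m ~ x`, `b` and `c'` from `y ~ m + x`, `c` from `y ~ x`, indirect effect
`a·b`, and the exact OLS identity `a·b + c' = c`. Confidence intervals come
from a percentile bootstrap over 10,000 case resamples by default —
resampling subject triples makes no homoskedasticity assumption and matches
the widely used macro's default; bias-corrected variants are deliberately
not the default. Degenerate resamples (a constant column) are redrawn and
counted. Both unstandardized coefficients and standardized ones (z-scored
inputs, same resamples) are returned, because published reports mix the two
scalings. Calibration facts the acceptance suite recomputes: under a
boundary null (mediator related to the predictor, outcome independent) the
95% CI excludes zero at close to the nominal 5% rate; under the complete
null the product statistic is well known to be conservative; and percentile
intervals at n ≈ 100 cover a true indirect effect at a rate a point or two
below 95%, as the bootstrap literature documents.

## Determinism and problem sizes

Every stochastic routine takes an explicit seed; pipeline stages derive
sub-seeds from the master seed by fixed offsets, so identical configuration
gives byte-identical output tables. The simulation-based checks run at
deliberately reduced but well-powered sizes chosen as part of the package's
own test design: 500 null cohorts (n = 40, 1,000 voxels, 499 permutations)
for family-wise error validity; 200 cohorts (n = 104, planted r = 0.35) for
cluster recovery; 1,000 datasets for the commonality identity; 1,000 null
and 500 effect replicates (499 bootstraps each) for mediation calibration.
`scripts/acceptance.R` re-runs the same battery from scratch at a given seed
and writes the resulting quantities as JSON.
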