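---
title: "Adaptive optimization of task-fMRI preprocessing pipelines"
author: "npairsopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive optimization of task-fMRI preprocessing pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Task-fMRI preprocessing is a long chain of optional noise-correction steps
-- motion correction, censoring of displacement spikes, physiological
regression, slice-timing correction, detrending, global-signal removal --
and the best combination varies across subjects, sessions and task designs.
Applying one fixed "conservative" recipe to everyone leaves residual noise
in some runs and removes task signal from others.  `npairsopt` treats the
pipeline itself as a model-selection problem: it enumerates every
combination of the optional steps, scores each combination on a single run
with split-half resampling, and selects pipelines per run, per cohort, or
conservatively.

## Metrics: split-half prediction and reproducibility

A run is split in time into two halves.  A predictive model -- Gaussian
naive Bayes (GNB) or canonical variates analysis (CVA) in a `k`-dimensional
PCA subspace -- is trained on each half and tested on the other:

* **Prediction** `P` is the mean posterior probability that held-out scans
  are assigned their true condition (chance = 1/number of classes).
* **Reproducibility** `R` is the Pearson correlation over voxels between
  the two half-maps (GNB sensitivity maps or CVA eigenimages).
* `gSNR = 2R/(1-R)` is a monotone transform of `R`; the package also
  offers the square-root form used elsewhere in the NPAIRS literature
  (`gsnrFromR(form = "sqrt")`), but reports the linear form by default.
* `D = sqrt((1-P)^2 + (1-R)^2)` measures distance from ideal performance
  (P = 1, R = 1); `D` is the default selection criterion.
* The half-map pair also yields a reproducible Z-scored SPM (`rspmZ`):
  signal axis `(m1+m2)/sqrt(2)` scaled by the voxelwise SD of the noise
  axis `(m1-m2)/sqrt(2)` (floored at 1e-12).

Block designs are decoded as 2-class problems; event-related designs label
each scan by its peristimulus lag within a 9-TR window, giving a 9-class
problem whose first GNB contrast / CVA eigenimage reflects the primary
haemodynamic response.

With thousands of voxels the joint GNB posterior saturates toward {0, 1},
so `P` approaches the fraction of correctly classified scans; this is the
default, with a per-voxel-averaged posterior available via
`posterior = "voxelwise"`.

## The pipeline grid

The ordered steps are: (1) minimum-displacement reference volume (always),
(2) rigid motion correction, (3) censoring, (4) RETROICOR, (5) slice-timing
correction, (6) 6 mm Gaussian smoothing (always), (7) non-neuronal tissue
mask (always), (8) Legendre detrending of order N = 0..5, (9)
motion-parameter PC regression (> 85% of motion variance), (10) global
PC#1 regression, (11) task-design regression, (12) data-driven
physiological denoising, (13) the analysis model.  Steps 8--11 are fitted
jointly in one GLM and only the nuisance partial fit is subtracted, so a
task regressor in the model protects task-coupled variance from
over-regression.  Eight binary flags times six detrend orders give
2^8 x 6 = 1536 GNB pipelines; CVA multiplies by k = 1..10 for 15360.  Step
order never changes; a flag only decides whether its step runs.

Selection rules:

* **CONS** -- the conservative set (steps 2--5, 8 with linear detrending,
  9).  Duration-based heuristics that scale the detrend order with run
  length would give order 2 for a 192 s run; the conservative recipe here
  fixes order 1 (strictly linear), keeping it a single literature-style
  baseline.
* **FIX** -- rank all pipelines by `D` within each run (rank 1 best), take
  each pipeline's median rank across runs, pick the minimum (ties: lower
  mean rank, then canonical grid order).  The ranking scalar is `D`,
  chosen for consistency with the stated goal of smallest average `D`.
* **IND-P / IND-R / IND-D** -- per-run argmax `P` / argmax `R` / argmin
  `D` over artifact-eligible rows.

Because IND optimizes per run over the whole grid, `P(IND-P) >= P(s)`,
`R(IND-R) >= R(s)` and `D(IND-D) <= D(s)` for *every* grid member `s`
(including CONS and FIX) whenever artifact rejection is off -- the test
suite checks this exhaustively on a 96-pipeline reduced grid.

### Motion-artifact rejection

Motion-corrupted SPMs concentrate weight on the brain edge.
`edgeArtifactScore` compares mean |Z| on the 1-voxel boundary shell of the
brain mask against the interior: 0.5 means no edge preference, and rows
scoring above 0.6 (a threshold calibrated so that i.i.d.-noise maps score
0.5 +/- 0.05) are excluded from IND selection.  Caveat: on strongly
down-scaled grids the planted activation itself reaches the 1-voxel shell,
so genuine activation maps can score near the threshold; the
forced-optimality and cohort-recovery properties are therefore evaluated
with rejection disabled, and rejection never flags every row (it disables
itself with a warning instead).

## The synthetic cohort generator

Every downstream stage is testable without external data because
`generateRun`/`generateCohort` produce 4D BOLD series with a fully known
composition:

* **Signal**: percent-signal-change amplitude times the HRF-convolved task
  design on a canonical three-blob active mask shared across subjects (so
  group-level overlap is meaningful).  The generator and the analysis use
  the same canonical double-gamma HRF (peak ~5 s, undershoot ~15 s, ratio
  1/6), so noise-free recovery is exact and pipeline effects are isolated.
* **Noise families**, each expressed in percent of the baseline intensity
  (100): polynomial drift (one shared Legendre timecourse, N(0,1) voxel
  weights), cardiac + respiratory quasi-periodic series sampled at each
  slice's acquisition time, a spatially uniform AR(1) global component,
  and AR(1) white noise with mild spatial smoothness rescaled to its exact
  per-voxel SD.  Each family's mean temporal variance on null voxels
  matches its configured budget within 20%.
* **Motion**: per-axis random-walk rigid motion applied by trilinear
  resampling (small amplitudes, <= 1 voxel, so the simplified
  Nelder-Mead/SSD motion correction can succeed), plus one-scan
  displacement spikes (>= 2 voxels with a 2% global intensity offset)
  that exercise both censoring pathways.

Defaults are desk-scale: 24 x 24 x 12 voxels of 3 x 3 x 5 mm, TR 2 s, 96
scans with 24 s alternating blocks (recognition-like); 20 s block
(trail-making-like) and sparse 9-TR-window event (sustained-attention-like)
designs are also built in.  Cohorts draw heterogeneous per-subject noise
profiles (drift order 1--4, drift 0.5--2.5%, physio 0.2--1.2%, motion walk
0.01--0.08 mm, 0--2 spikes, global 0.2--1.5%, white 1.5--2.5%, AR(1)
0--0.4) and couple per-run behaviour linearly to the planted amplitude.
Ranges are calibration choices -- realistic spreads for young healthy
cohorts -- not values taken from any dataset.

What the generator does *not* emulate: vascular geometry, k-space/multi-coil
physics, susceptibility distortion, spatial normalization (synthetic
subjects share a grid), or the spatial covariance structure of real brain
networks.  Passing tests show the estimators and selection rules behave as
designed under a known forward model, not that any particular pipeline is
best for real data.

## Validation stages

* **Activation overlap** (`fdrMask`, `jaccard`): two-tailed p from |Z|
  (SPMs carry signed task-negative regions), Benjamini--Hochberg step-up at
  q = 0.05, then intersection-over-union of the active masks.
  Within-subject overlap pairs run-k (test) only with run-k (retest) to
  avoid learning confounds; between-subject overlap takes each subject's
  mean Jaccard with all others per session and run, pooling rows across
  sessions (27 x 2 = 54 test rows, plus 20 x 2 retest rows = 94).
* **Group eigenimages** (`pc1EigenimageZ`): 50 random half-splits of the
  SPM stack; the first *uncentred* singular vector of each half (centring
  would subtract exactly the stable mean pattern being sought),
  sign-aligned to positive mean loading, combined via `rspmZ` and
  averaged.
* **Behavioural PLS** (`plsSplitHalf`): 100 random half-splits (stratified
  by session when available); each half's salience map is the centred SPM
  matrix projected onto its standardised behaviour vector; `rho_behav`
  cross-validates by correlating one half's brain scores on the *other*
  half's salience with its own behaviour; `gSNR_behav` comes from the
  salience-pair reproducibility.  SPMs are centred but not z-scored before
  the cross-covariance.  Pipelines are compared by 1000 bootstrap draws
  over the 100 split-half estimates (Delta gSNR, Delta rho; empirical
  p = 1 - fraction positive).
* **Outlier screening**: behavioural rules (RT < 100 ms, accuracy < 50%,
  harder task faster than easier); fMRI maps whose mean RV coefficient
  with the other maps falls below Q1 - 1.5 IQR.

## Numerical choices

* Detrend columns are sampled Legendre polynomials re-orthogonalised by QR
  on the scan grid, so discrete orthogonality is exact while the span
  (polynomials of degree <= N) is unchanged.
* Censoring statistic: robust z (median/1.4826 MAD) of the frame-to-frame
  Euclidean displacement (full PC space preserves it), then each scan's
  score is the *smaller* of its two adjacent z values -- an isolated spike
  elevates both adjacent jumps, so only the spike itself is flagged;
  threshold z > 4; framewise displacement from motion parameters (50 mm
  rotation arm) enters the same rule when available.  Flagged scans are
  linearly interpolated between the nearest unflagged neighbours.
* Motion estimates are the negated correcting transforms (exact for
  translations, small-angle approximation for rotations; planted motion is
  <= 1 voxel).
* RETROICOR: cardiac phase linearly interpolated between detected peaks;
  respiratory phase by histogram-equalised signed amplitude; 8 regressors
  (sin/cos, orders 1--2, both modalities) fitted per slice at that slice's
  acquisition times.
* Slice timing: Fourier phase shift to slice-time 0, Nyquist bin kept
  real; no windowing.
* CVA within-class scatter always carries a 1e-6 x trace/k ridge;
  canonical directions are scaled to unit within-class variance, making
  the shared-covariance posterior an identity-covariance Gaussian.
* Scan and voxel indices are 1-based throughout the R API; file outputs
  (events TSV) use seconds from the first scan's acquisition.
* Step-7 masks are computed once per run inside `evaluateGrid` (from the
  smoothed data with no optional steps) so every pipeline is compared on
  one consistent voxel set.

## Problem sizes used by the tests and acceptance script

Operator tests run on 8--16 voxel grids with 24--96 scans.  The cohort
recovery properties use 10 subjects x 2 runs at the default grid with a
24-pipeline reduced grid containing CONS (free flags: motion correction,
global PC1, task regressor; N in {1, 3, 5}); the exhaustive
forced-optimality check uses a 96-pipeline grid on one run.  The
acceptance script mirrors these sizes.  These are the package's desk-scale
study conditions; the full 1536/15360 grids remain the default contract of
`enumeratePipelines`.

## Known limitations

* The data-driven physiological step is a principled stand-in (noise-mask
  PC regression) exposing the same pipeline flag as a full multivariate
  physiological model; the interface allows plugging a faithful
  implementation later.
* Motion correction is simplified (SSD + Nelder-Mead, trilinear); it is
  not a replacement for production registration tools on large-amplitude
  real-data motion.
* Split-half evaluation is within-run only; cross-run training is out of
  scope, as are step-order permutation and smoothing-scale search.
* The bootstrap comparison conditions on the two fixed split-half sample
  sets; with identical inputs its positive fraction is ~0.5, but across
  independent null replications the fraction is diffuse -- its p-values
  are only approximately uniform under the equivalent-pipeline null.
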