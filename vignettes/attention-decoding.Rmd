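---
title: "Decoding covert visuospatial attention: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding covert visuospatial attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldbci)
```

This vignette is the package's account of the science it implements: the
signal model, the estimators, every tunable that matters, and the design
choices that were genuinely open, with the reasons they were settled the
way they were.

## The decoding model

A subject attends left, right, or center while fixating centrally.
Attention to one side raises the BOLD signal in contralateral retinotopic
visual cortex and lowers it at the ipsilateral occipital pole (the foveal
representation is suppressed during peripheral attention). The decoder
turns this into a scalar per scan: two regions of interest, one per
differential contrast, are averaged and combined as

$$\mathrm{CS}(t) = 100\,\frac{S_R(t) - B_R}{B_R} -
  100\,\frac{S_L(t) - B_L}{B_L},$$

with $S_R, S_L$ the detrended ROI means and $B_R, B_L$ baselines from the
center condition. Because ROI$_R$ collects voxels high on *right−left*
(activated by right attention **or** deactivated by left attention) and
ROI$_L$ the mirror set, both effects push CS in the same direction —
positive for right attention, negative for left.

## Stage by stage

**Schedules.** Trials tile the run contiguously; the only constraint the
paradigm imposes on the pseudo-random order is that no two adjacent
attention trials share a side. The exact sampler is unspecified by the
paradigm, so `make_schedule()` draws each trial uniformly among the
conditions with remaining quota (excluding a same-side repeat), restarting
on dead ends; any constraint-satisfying order can occur, and draws are
seed-reproducible. Defaults: localizer 8+8+8 trials of 8 scans plus one
initial center trial (200 scans); feedback 10+10+10 trials of 10 scans
(300 scans); TR 1.62 s.

**Synthetic BOLD runs.** `simulate_bold()` builds
`baseline × (1 + drift + response + noise)` per voxel: an ellipsoidal
1000-intensity "brain", a linear drift (default 1 %/min) with an optional
slow cosine term of per-voxel random phase (so the detrender faces a
nonlinear target — real scanner drift is not a straight line), Gaussian
white noise (default 3 % per scan), and condition responses obtained by
convolving the block indicators with a canonical double-gamma HRF (peak
5 s, undershoot 15 s, undershoot ratio 1/6) scaled so a planted effect of
`effect_pct` percent produces that peak percent change. Defaults plant
2 % activations and −1 % occipital-pole deactivations; with 3 % noise the
localizer t-values at the planted sites land around 3–5, the regime a
high-field scanner delivers for this task. The generator does **not**
emulate physiological noise spectra, spatial noise correlations,
field-inhomogeneity artifacts, or behaviorally variable attention, so
passing tests demonstrate correctness of the pipeline, not expected
performance on human data.

**Motion correction.** `register()` minimizes the mean squared intensity
difference to the first volume after blurring both images (σ = 1 voxel),
over three rotations about the grid center and three translations. Two
details matter numerically. First, the SSD is evaluated on a fixed
interior region (3-voxel margin): if boundary voxels enter and leave the
field of view as parameters change, the objective jumps discontinuously
at the optimum. Second, trilinear interpolation biases the optimum by a
noticeable fraction of a voxel (its implicit smoothing is
offset-dependent), so the deterministic mode refines the trilinear
solution against the exact cubic B-spline interpolant of the blurred
moving image (Unser recursive prefilter, mirror boundaries); the final
resampling of the unblurred image is also cubic B-spline. A stochastic
mode (fresh 2000-voxel subsample per iteration, 1/k step decay, 50
iterations) mirrors the classical real-time configuration and falls back
to the identity if it ends worse than it started, so the SSD never
increases. Rotation parameterization is Euler angles in the fixed order
Rz·Ry·Rx about the grid center; the scaled parameter space (rotations
multiplied by the half-grid lever arm) keeps the six parameters
comparably conditioned.

**Incremental GLM.** The mass-univariate model is accumulated as
$X'X$, $X'y$, $y'y$ — constant work per scan and *exactly* the batch
sufficient statistics after any number of updates (the equivalence is
enforced against an independent QR-based batch fit, and against `lm()`
on single voxels). Design: right and left attention regressors, linear
drift, intercept. Two open points were settled as follows: an explicit
intercept is included because t-statistics require the mean to be
modeled, and the attention regressors are HRF-convolved by default
(consistent with the generator) with a raw-boxcar toggle, since block
designs of this length are robust to that choice. Degenerate voxels get
a total ordering rather than NaN: zero-variance voxels score t = 0, and
zero-residual voxels with a nonzero contrast estimate are capped at
±10⁶ — downstream top-k selection needs every voxel rankable.

**ROI selection.** The brain mask thresholds the smoothed mean volume at
30 % of its 98th intensity percentile (the paradigm states no number;
this is insensitive to the bright-voxel tail), fills enclosed cavities,
and zeroes the two most anterior coronal slices. Per side the 500
highest t-values inside the mask are kept (ties broken by ascending
linear voxel index so selection is deterministic) and 6-connected
(face-adjacent) clusters under 5 voxels are removed. Baselines average
the **raw** localizer signal over center scans, excluding the first 3
scans (4.86 s) of center trials that follow an attention trial; raw
rather than detrended was chosen because the feedback-time detrending
operates on deviations anchored at these baselines, which makes the
distinction second-order — a detrended option would change baselines by
well under the noise level on any run the generator produces.

**Detrending and the control signal.** The smoothness-priors detrender
solves $(I + \lambda^2 D_2'D_2)\,\tau = z$ per voxel and returns
$z - \tau$; constants and straight lines lie in the null space of $D_2$
and are removed exactly, and $\lambda = 0$ returns zeros identically.
λ defaults to 500 (configurable): at TR 1.62 s this passes the 16-s
block responses while absorbing drifts over minutes. The reference path
re-detrends the full available series (localizer + feedback so far) at
every new scan, exactly as a real-time system that appends each volume
would. Because the residual is zero-mean, the ROI level is anchored at
the localizer baseline ($S = B + \bar d$) before Eq. CS is applied — the
percent terms then measure detrended deviations in baseline units. The
SD-normalized variant divides each percent term by its localizer
standard deviation, trading absolute calibration for lateral symmetry.

**Thresholding.** Fixed thresholds (±1.5, ±2.5, ±4 percent) or adaptive:
with labels shifted 3 TRs (4.86 s) for the hemodynamic delay, the first
rightward threshold is the smallest observed CS value whose training FPR
over left-or-center scans is ≤ 0.2 (the empirical FPR is a step function
of the threshold, so searching the observed values is exact — verified
against a brute-force sweep); mirrored leftward. The second and third
levels scale from the first by the fixed-scheme ratios 2.5/1.5 and
4/1.5, which reproduce the fixed scheme at θ₁ = 1.5; if an estimated
first threshold is zero or crosses zero, ratio scaling would invert the
ordering, so the fixed-scheme gaps (1.0 and 2.5) are added instead. Only
the first pair enters the rate metrics, so this choice affects feedback
coloring only. A biased control signal can make the two first thresholds
land on the same side of zero; rates are computed per side
independently, so this is well-defined throughout.

**Scoring.** TPR/FPR per scan after the 3-TR shift; scans whose shifted
label falls before the run start are dropped from numerator and
denominator. FPR is reported with and without center scans — the BOLD
undershoot after an attention block rebounds CS across the opposite
threshold during center trials, an artifact of hemodynamics rather than
of the control strategy. ROC curves sweep the first threshold from −1 to
5 (right) and 1 to −5 (left). Trial classification uses the single scan
at a fixed within-trial index with no shift (matching how per-volume
accuracy is usually displayed), three-way: above θ₁R → right, below
θ₁L → left, else center. The Wolpaw rate takes its P ∈ {0, 1} limits by
continuity. Dice of two empty voxel sets is defined as 1.

**ECoG.** Band power is Welch's estimate (1-s Hann segments, 50 %
overlap — the paradigm fixes only the band and the 4-s window) on
common-average-referenced signals. "The standard deviation over all
three directions" in the amplitude condition is read as the pooled SD of
the channel's training values (unity after normalization); the
alternative reading (SD of the three class means) is exposed as
`sd_mode = "class_means"`. Scores are sign-adjusted by default so a
*decrease* in gamma power still votes for its class;
absolute-magnitude scoring is a flag. Ties take CENTER > RIGHT > LEFT,
and a fold whose every channel set is empty predicts the
training-majority class. The margin grid defaults to 50 values from 0 to
the 95th percentile of between-class mean gaps, recomputed per fold from
training trials only; normalization statistics likewise never see the
held-out trial (asserted in the tests by recomputation).

## Problem sizes in the tests

The test suite and the acceptance script run the full pipeline on
32×32×16 grids (the full 96×96×35 acquisition matrix is supported by
configuration) with the standard 200-scan localizer and 300-scan
feedback design; registration tests use 16³ smooth phantoms; GLM
equivalence is checked over 20 simulated runs; the adaptive-threshold
estimator over 50 traces; the ECoG permutation null over 100 label
permutations of the 20/20/39-trial composition with a 15-point margin
grid. These sizes were chosen so that each property is measured with
comfortable statistical margin while a complete check remains a
desk-scale computation.

## Known limitations

* The generator's noise is white in space and time; autocorrelation
  (prewhitening) is deliberately absent from the GLM, matching the
  real-time design it mirrors.
* The registration wall-clock target of a real-time system is out of
  scope; the implementation optimizes accuracy and reproducibility, not
  throughput.
* Feedback coloring is an enumerated label; no stimulus rendering or
  scanner transport is emulated.
* Raw ECoG voltage synthesis is not provided; the generator works at
  band-power level, which is where the classifier operates.
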