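---
title: "Dynamic ICG perfusion analysis: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic ICG perfusion analysis: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgflow)
```

## The problem

Indocyanine green (ICG) is a protein-binding near-infrared fluorophore
that is cleared by the liver: after an intravenous bolus, healthy
parenchyma takes up and retains the dye while colorectal liver
metastases (CRLM) — perfused but not ICG-concentrating — show a fast
inflow followed by prompt washout. Recording the first ~90 s after a low
(0.05 mg/kg) intraoperative dose with a dual-channel (white light + NIR)
laparoscope therefore turns tissue identity into a *curve-shape*
problem: each region of interest (ROI) yields a time–fluorescence curve
whose milestones (time to peak, outflow slope, centre of mass, ...)
separate lesion from liver within a single patient, without inter-patient
or inter-device intensity calibration.

`icgflow` implements the full desk-side pipeline around that idea:

1. **trace extraction** — template tracking of ROIs in the white-light
   channel and extraction of the synchronous NIR mean intensity at 30
   fps (with a fixed-ROI path for green-overlay-only systems, whose
   frames are reduced to their green channel);
2. **milestone features** — the twelve curve features with the mapped
   reference-peak rule for healthy tissue;
3. **ROI classification** — an exhaustively tuned decision tree under
   10-fold cross-validation;
4. **field mapping** — landmark matching, thin-plate-spline (TPS)
   stabilization at 7 fps, per-pixel milestone heatmaps and unsupervised
   clustering of piecewise-constant profile summaries;
5. **cohort statistics and microscopy quantification**;
6. **a synthetic angiogram generator** that stands in for the clinical
   recordings, which are not publicly deposited.

## The kinetic model

Each tissue class follows a gamma-variate bolus,
$$F(t) = b + A\,\Big(\frac{\tau}{t_p}\Big)^{\alpha}
          e^{\alpha\left(1 - \tau/t_p\right)},\qquad \tau = t - d,$$
with baseline $b$ (g.u.), arrival delay $d$ (s), time-to-peak $t_p$ (s),
amplitude $A$ (g.u.) and unitless sharpness $\alpha$; $F \equiv b$ for
$t \le d$. The form is the standard indicator-dilution family: few
parameters, exact peak $b + A$ at $t = d + t_p$, unimodal.

### Calibration to the published milestones

`calibrateKinetics()` inverts the family against milestone targets:
$d + t_p$ from the target peak time, $\alpha$ from the end/peak
intensity ratio at the window end, and — when a time-ratio target is
given — $d$ from the half-rise time by root finding. An analytic
solution is then refined by a short fixed-point loop *through the actual
extractor* (sampled at 30 fps, 1 s smoothing), so discretization and
smoothing biases are calibrated out; the result must reproduce every
supplied target within 2 %, else calibration fails loudly.

The published cohort means are **jointly infeasible** for any single
unimodal gamma-variate, in two places:

* for CRLM, a −2.4 g.u./s outflow over the first 10 s after the peak
  cannot coexist with an end intensity at 83 % of the peak 66 s later;
* for healthy liver, a half-rise at 0.127 of an 82.6 s peak time cannot
  coexist with an end/peak ratio of 0.97 (that requires a fast-then-slow
  biphasic rise).

Curve shapes beyond the milestones are unconstrained, so calibration
targets the subset that is feasible and that the validation actually
consumes: CRLM `{tmax, fmax, fEnd, timeRatio}`, healthy
`{tmax, fmax, fEnd}`. Consequences worth knowing: the synthetic CRLM
washout is gentler than the printed slope-10 (its *sign* is preserved),
the synthetic healthy time ratio is ~0.65 rather than 0.127, and the
synthetic healthy intensity-value skew is positive where the cohort
prints negative (real parenchyma saturates early; the late-rising
calibrated curve cannot). Sign-pattern tests therefore use the CRLM
curve and an explicitly saturating curve, and no test asserts that the
synthetic cohort reproduces the kurtosis/skew significance rows.

```{r kinetics}
kineticDefaults()[c("lesion", "healthy")]
```

### Per-ROI variability

ROI realizations jitter the class parameters with mean-one log-normal
factors: one on the amplitude, one on the *time scale* ($d$ and $t_p$
jointly, preserving the time ratio), one on $\alpha$. The amplitude and
time CVs equal the published SD/mean per class (e.g. 0.56 for CRLM peak
time), so extracted milestone spreads approximate the cohort SDs; the
shape CV (0.15) is a modelling choice. Two censoring effects are handled
in closed form so that *extracted* means stay calibrated:

* **window cap** — a realization peaking beyond the 90 s window yields
  an extracted peak time at the window end; the time jitter is rescaled
  so the mean of the capped variable equals the nominal class value
  (material for healthy liver, whose peak sits 7 s from the window end);
* **saturation** — the 8-bit ceiling would clip strong realizations and
  drag the smoothed argmax early; amplitude jitter is drawn from a
  log-normal truncated below the ceiling (mirroring the low-dose
  protocol, which was chosen precisely to avoid saturation), rescaled to
  truncated mean one. The extracted spread of peak intensity is
  accordingly somewhat narrower than the printed SD for healthy liver.

Trace noise defaults to 0.2 g.u.: the residual of averaging ≥ 100 pixels
with ~2 g.u. sensor noise. The benign cyst class shares the healthy
*temporal* profile at strongly reduced amplitude (45 g.u.): cyst fluid
accumulates little ICG, so timing maps show no margination while
absolute intensity separates the class — the property that lets the
classifier recognize all cyst ROIs. The rim class is healthy kinetics
with a 1.2× amplitude boost and slowed washout (early rim enhancement).

## Milestone features

All twelve features are computed per trace, on a clock re-zeroed at the
window start:

| feature | definition | units |
|---|---|---|
| `tmax` | earliest argmax of the 1 s-smoothed trace | s |
| `fmax` | smoothed maximum | g.u. |
| `fEnd` | smoothed final sample | g.u. |
| `upslope` | $(F_{max} - F(t_{on}))/(t_{max} - t_{on})$, onset at 10 % of dynamic range | g.u./s |
| `timeRatio` | first time the baseline-subtracted trace reaches half amplitude, over `tmax` | — |
| `delta10` | $F(t^\* + 10) - F(t^\*)$ | g.u. |
| `slope10/20/60` | $(F(t^\*+k) - F(t^\*))/k$ | g.u./s |
| `kurtosis`, `skew` | sample excess kurtosis $g_2$ / Fisher–Pearson $g_1$ of the intensity values | — |
| `com` | $\sum t_i F_i / \sum F_i$ on raw samples | s |

The anchor $t^\*$ is the trace's own peak for CRLM (and benign) traces;
healthy traces, which lack an early peak, use the **mapped reference
peak**: the patient's CRLM peak time, averaged when several lesion ROIs
were tracked (`referencePeak()`, applied per patient by
`computeFeatureTable()`). `delta10 = 10 * slope10` holds exactly by
construction. Undefined milestones (a flat trace; an anchor within $k$
seconds of the window end) propagate as `NA`, never as zeros.

Conventions the source work leaves open, fixed here: baseline = mean of
the first second (used only for half-time and onset; peak and end
intensities are reported raw); upslope denominator from the 10 %-onset
point; excess-kurtosis convention; earliest-argmax tie-break; smoothing
= 1 s centered moving average with shrinking edge windows (COM and
moments on raw samples).

## ROI classification

`optimizeTree()` grid-searches a classification tree over maximum depth
1–10, minimum leaf size {1, 2, 5, 10, 20} and split criterion
(gini/information), scoring each candidate by pooled out-of-fold
accuracy under 10-fold cross-validation and refitting the winner on the
full table. Folds are assigned by a 32-bit FNV-1a hash of
`roiId` + seed: reproducible, row-order independent, and tolerant of
classes smaller than the fold count (the 6-cyst class cannot populate
ten folds; the function warns rather than silently changing the
protocol). Ties prefer the smaller depth, then the larger leaf —
the least-variance candidate. Missing features are imputed with
training-fold medians, never across the train/validation boundary. An
optional roster mode adds linear discriminant analysis and k-NN to the
search. `stratifiedSplit()` provides the 80:20 ROI-level hold-out
(optionally by patient), and `evaluateClassifier()` reports the
confusion matrix, accuracy, CRLM-positive PPV and per-class TPR/FNR to
one decimal.

## Field mapping

Stabilization selects frames at 7 fps by nearest-index selection
(preserving 8-bit values, rather than averaging), takes the middle
selected frame as reference (minimizing accumulated drift), and tracks
variance-maxima landmarks from the reference outward with per-landmark
prediction. Matches are scored by normalized cross-correlation with
parabolic sub-pixel refinement, filtered by iterated consensus against a
similarity transform (2 px threshold), and interpolated to all pixels by
a thin-plate spline ($U(r) = r^2\log r$; $\lambda = 1$ by default to damp
landmark noise, $\lambda = 0$ retained for the affine-exactness
property). The NIR stack is resampled through the warp (bilinear);
pixels leaving the field of view in any frame form the invalid grey
border. Frames with too few landmarks reuse the previous warp up to
`maxGap` consecutive frames, then stabilization fails loudly.

Per-pixel maps: centre of mass on raw samples; outflow slope between the
pixel's own smoothed peak and peak + 10 s, `NA` when the peak leaves no
10 s headroom — which is the *typical* state of healthy liver in a 90 s
window. An optional global anchor (`tRef`) applies the ROI-level mapped
reference-peak rule field-wide; with a lesion-peak anchor, healthy pixels
show positive slopes and lesions negative, reproducing the red/blue
dichotomy of the slope maps. Clustering summarizes each valid pixel by
the level vector of an *exactly optimal* piecewise-constant segmentation
(dynamic programming, default 5 segments, curves block-averaged to ≤ 90
samples to keep the exact DP affordable) or by its (COM, slope) pair,
then k-means (default k = 3: lesion / rim / background; fixed seed, 10
restarts) with labels relabeled by ascending cluster-mean COM so that
label 1 is always the earliest-perfusing cluster. COM maps render on
viridis with delayed COM at the yellow end; slope maps on a diverging
scale, negative red, positive blue, centered at zero; invalid pixels
grey.

## Cohort statistics and microscopy

Shapiro–Wilk normality and two-sided Mann–Whitney U comparisons (exact
for small tie-free samples, normal approximation with tie correction
otherwise) feed `buildMilestoneTable()`, which reports per-feature group
means ± sample SD with raw p-values starred at 0.05 — no multiplicity
correction, mirroring the cohort report format. Synthetic microscopy
sections emit ~507 a.u. signal/area in healthy parenchyma vs ~2.5 in the
lesion (the reported scale, in arbitrary units), with multiplicative
mean-one log-normal acquisition noise drawn independently of the stained
flag; staining divides the emission field by the attenuation factor
(default 6.5) *before* noise, so a same-seed pair recovers the factor
exactly and independently-seeded pairs recover it up to noise.

## The synthetic scene generator

`renderSequence()` renders a dual-channel pair in tissue coordinates —
static liver-like white-light texture (large-scale shading + mid-scale
blobs + speckle; the mid scale is what survives bilinear resampling and
makes landmarks localizable), per-pixel gamma-variate NIR curves per the
class map (elliptical lesion, optional rim annulus, optional non-perfused
border) — and then samples both channels through the motion model: a
global affine random walk (camera) plus a single-frequency sinusoidal
displacement field (respiration), identical in both channels. Sensor
noise is added per frame and everything is clipped to [0, 255] and
quantized to 8 bits. The ground-truth record carries the class map,
per-pixel kinetic parameters, the exact motion trajectory (queryable via
`trueSourceCoords()` / `trueDisplacement()`) and the noise-free curves.

What the generator does **not** emulate: photorealistic anatomy,
specular highlights and occlusion, illumination drift, non-stationary
breathing, cirrhotic or otherwise abnormal non-malignant parenchyma, 3-D
deformation, device-specific tone curves. Passing tests therefore
demonstrate correctness of the *algorithms* under the stated motion and
kinetic model, not clinical performance on real recordings; the
classifier's synthetic accuracy in particular inherits the generator's
class separations and says nothing about prospective patients.

## Problem sizes and numerical choices

Validation runs on deliberately small instances: 64 × 48 px scenes at 30
fps for 90 s (2700 frames), cohorts of 132 + 24 + 6 ROI traces of 2700
samples, stabilization at 7 fps (630 selected frames), 200-trace
recovery runs. The milestone-recovery checks use a 2-SEM band around the
published means at n = 200; the classifier check requires ≥ 97.2 %
out-of-fold CRLM recall and 6/6 cyst ROIs on the calibrated cohort.
Numerical details: TPS systems are solved densely (≤ ~50 landmarks);
NCC denominators below 1e−9 are treated as featureless; sub-pixel
refinement is clamped to ±0.5 px and suppressed at perfect integer
alignment; the window is half-open `[0, 90)` s so a 90 s trace holds
2700 samples at 30 fps (2698 remains configurable); coordinates are
1-based (row, col) in R and 0-based in the JSON interchange format.

## Known limitations

* The gamma-variate family cannot reproduce every printed milestone
  simultaneously (see calibration above); curve-level realism is limited
  to the targeted subset.
* ROI tracking is translation-only by design; rotation or strong
  deformation within an ROI degrades it (the full non-rigid model lives
  in the stabilizer).
* The exact piecewise-constant DP is quadratic in the (coarsened) curve
  length; raising `pwcSamples` far beyond ~150 becomes slow.
* With only six cyst ROIs, the cyst column of any confusion matrix is
  fragile; the cohort-level cyst result should be read as a sanity
  check, not a validated sensitivity.
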