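---
title: "Estimating pig live weight from top-view masks: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pig live weight from top-view masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pigwt` estimates the live weight of finishing pigs from top-view binary
masks of their backs. This vignette is the package's own account of the
method: the model at each stage, the conventions and tolerances chosen
where several were defensible, what the synthetic generator does and does
not emulate, and the limitations that follow.

## The pipeline

An overhead camera and an upstream instance-segmentation network (outside
this package's scope) produce one mask raster per frame. The package then
runs four stages:

1. cleanup: binarize, open with an elliptical element, keep the largest
   8-connected component, trace the boundary;
2. features: `Area`, `Per`, `PBL`, `PHW`, `Ecc`, `Dev` per frame;
3. correction: boosted regressions map `(PBL, PHW, Dev)` to measured body
   length, hip width and camera-to-back distance, fixing the bias that
   spine bending puts into the projected pixel lengths;
4. regression: a strategy × method grid predicts weight from the feature
   sets, with a seeded 7:3 frame split, optional five-fold grid-search CV
   on the training side only, and MAE / MAPE / RMSE / R² on the test side.

## Mask processing conventions

**Binarization.** A pixel is foreground iff its intensity exceeds the
threshold (default 0); colored multi-label rasters collapse by channel
maximum first, so any nonzero instance label counts as pig. Exactly one
animal per frame is assumed; per-label selection is out of scope.

**Opening.** The "elliptical element of size 70" is read as the discrete
disc `{δ : |δ| ≤ size/2}` — a 71×71 bounding box for size 70. Whether such
a size names a diameter or radius is genuinely ambiguous; diameter is the
default and the size is a plain argument. Erosion and dilation are
computed through an exact squared Euclidean distance transform, which is
mathematically identical to the sliding min/max filter for a Euclidean
ball element (the suite asserts bit-exact equality against a literal
min/max oracle). Pixels beyond the frame border count as background, so
opening is anti-extensive and idempotent. At the default camera geometry a
finishing pig's back is ≈ 190 px wide — comfortably wider than the 70 px
element — while illumination specks are far smaller, which is the point of
the size.

**Connectivity and contours.** Foreground is 8-connected (background
4-connected). The boundary is traced with Moore-neighbour tracing,
clockwise, starting at the topmost-then-leftmost foreground pixel, with
Jacob's stopping criterion; this makes the contour, and hence the
perimeter, deterministic. Coordinates are 1-based `(row, col)`, the
language's native convention.

## Feature conventions

- **Area** is the foreground pixel count: each pixel one unit square.
- **Per** is the √2-weighted chain length of the traced contour. On smooth
  shapes this convention carries a known asymptotic over-estimate of about
  5.5% (a digitized circle of radius 100 measures ≈ 5.3% above 2πr); the
  tests assert the convention exactly on polygons and to 6% on discs. The
  bias is irrelevant downstream because the regressors only need a
  monotone size proxy.
- **PBL/PHW** come from the minimum-area rotated bounding rectangle of the
  foreground, computed by rotating calipers over the convex hull. Reported
  sides are the pixel-centre projection extents plus one pixel: exact for
  axis-aligned rectangles, and within about ±1 px for oblique ones (no
  additive convention is exact at every angle, because oblique lattice
  projections approach the true boundary arbitrarily closely). A dense
  0.25°-sweep oracle with the same convention agrees with the calipers to
  1% on random convex blobs.
- **Ecc** is `√(1 − λ₂/λ₁)` of the central second-moment matrix — the
  moment (not least-squares) ellipse fit: closed-form and deterministic. A
  16-px minimum area guards the moments.
- **Dev** is the background fraction `1 − Area/(H·W)`, exactly. Since the
  animal's image footprint shrinks with camera distance, `Dev` is the
  image-only proxy for depth. Note that at fixed frame size `Dev` is an
  affine transform of `Area`: deterministic tree learners therefore build
  identical models with or without it, and the `Dev` ablation (strategy
  "1b") only separates methods with feature subsampling, such as the
  random forest — where dropping `Dev` measurably hurts.

## Depth and the correction stage

The camera-to-back distance is `Hdep = Hg − (Hb + Hh)/2` with the camera
height `Hg` (145 cm default) and the measured body and hip heights; it is
a per-pig constant. The correction stage trains one Newton-boosted
regressor per target — body length, hip width, `Hdep` — from the image
features `(PBL, PHW, Dev)`.

Two points were genuinely open:

- **Is measured `Hdep` a correction input?** Source descriptions list it
  both as an input and as a quantity being estimated. Since at deployment
  only image features exist, the default inputs exclude it;
  `include_hdep_input = TRUE` restores the literal reading for setups
  where heights are measured at inference time.
- **Split hygiene.** The correction is trained on the training split only.
  Additionally, corrected features for *training* frames are produced
  out-of-fold (5 folds): a correction model corrects its own training
  frames almost perfectly, so feeding in-sample corrections to the weight
  model would train it on a cleaner feature distribution than it faces on
  test frames. The out-of-fold scheme (the same idea the stacking learner
  uses) removes that mismatch; on the default herd it cuts the strategy-2
  test RMSE from 2.14 to 1.81 kg. Test frames are always corrected by the
  full-training-split model, which is also the model kept for future
  frames.

## Native learners

The tree-ensemble learners are implemented in the package (the baseline
registry delegates only SVR, MLP and BP to `e1071`/`nnet`):

- **Trees** use greedy induction with variance-reduction impurity — the
  regression analogue of entropy information gain, which is undefined for
  continuous weights. Candidate thresholds are midpoints between distinct
  sorted values; ties break to the lowest feature index, then the lowest
  threshold, making every fit deterministic.
- **Forests** train each tree on a seeded bootstrap resample with
  per-split feature subsampling (default one third) and predict the exact
  arithmetic mean of the trees; default 200 trees, node size 5.
- **Boosting** is second-order (Newton) boosting of the squared loss:
  gradients `g = ŷ − y`, unit hessians, split gain
  `½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ)] − γ` with non-positive gains
  rejected, leaf weights `−G/(H+λ)`, base score `mean(y)`, update
  `ŷ ← ŷ + η·tree(x)`. Defaults: K = 300 rounds, η = 0.1, λ = 1, γ = 0,
  depth 4. The suite checks the single-leaf closed form, monotone training
  descent, and agreement with an independent exact-greedy implementation
  to 10⁻⁴.
- **Baselines**: least squares via QR; lasso by coordinate descent
  (tolerance 1e-8, standardized internally, checked against an independent
  solver); kernel ridge closed-form with an RBF kernel (γ = 1/d on
  standardized features); Adaboost.R2 with linear loss and weighted-median
  prediction; stacking with 5-fold out-of-fold base predictions
  (forest + boosting + kernel ridge) under a linear meta-learner.

Hyperparameter grids, when supplied, are searched exhaustively by mean
five-fold validation RMSE on the training split, ties keeping grid order.

## Evaluation metrics

MAE, MAPE (percent, undefined and rejected when an observed weight is
zero) and RMSE follow the standard formulas. For R² the baseline spread is
taken around the mean of the *observed* values, the standard coefficient
of determination; some sources print the formula with the mean of the
predictions, and `r2_baseline = "predicted"` reproduces that literal
variant. The 7:3 split takes `floor(0.7·n)` training rows. The default
split is by frame — mirroring a frame-level acquisition split, which lets
a pig appear on both sides and therefore rewards models that can
re-identify individuals; the by-pig mode (`split_mode = "pig"`) keeps all
frames of a pig on one side and is the setting to trust when the question
is generalization to unseen animals. Both are provided; results quoted in
this package use the frame split unless stated.

## The synthetic herd generator

The generator exists so every stage is testable without farm data. It
emulates the study conditions: 39 pigs, ~39 frames each (≈ 1.5k frames), a
145 cm camera, 1920×1080 frames.

**Biometry.** Body length, hip width, body height and hip height are
truncated normals with the herd table's means, SDs and ranges
(e.g. body length 126 ± 5.79 cm in [108, 137]); a shared latent size
factor gives all pairs correlation 0.6 (the table reports only marginals;
0.6 is a typical size-trait correlation in finishing pigs). Out-of-bounds
pigs are redrawn.

**Weight.** No weight-generating law is reported, so the generator uses
the allometric form `W = s·BL·HW·Hb·exp(ε)`, with `s` calibrated so the
trait means map exactly to the mean weight (122.81 kg) and `ε` a per-pig
log-scale residual of SD 0.03. Part of `ε` (coupling 0.8) is carried by
the pig's relative width minus relative length: fatter-than-frame pigs are
both heavier and relatively wider. This body-condition term is what makes
slender (high-`Ecc`) pigs lighter in the synthetic herd — the association
reported for real herds — which a pure shared-size-factor model produces
only weakly. Weights are clamped to the herd range [104, 138] kg (the
deterministic part alone can leave the range, so resampling cannot enforce
it).

**Shape and rendering.** A body is a capsule: centreline arc of length
`BL − HW`, cap radius `HW/2`, so tip-to-tip length is exactly `BL` and the
analytic area is `BL·HW + (π/4 − 1)·HW²`. Bending sweeps the centreline
along a circular arc with per-frame curvature |N(0, 0.004 cm⁻¹)| — a
half-normal, since only the occurrence of bending is documented, not its
distribution; 0.004 cm⁻¹ bends a 126 cm pig by up to ~30°. Pose is a
uniform rotation with jittered centering inside the frame. The pinhole
model scales by `focal_scale / Hdep` pixels per cm; `focal_scale = 400`
px·cm puts a finishing pig at ≈ 5.5 px/cm so the longest bodies span
~800 px at any rotation. A smooth two-harmonic radius wobble (default
1.5%) roughens the boundary. `Hdep` is constant per pig: no per-frame
posture variation of height.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: segmentation errors (the upstream network's
failure modes), occlusion and multi-animal scenes, RGB texture and
illumination, non-capsule anatomy (head, ears, tail), within-pig weight
change over the recording days, and frame-to-frame height variation.
Results on the synthetic herd validate the pipeline's mechanics and
internal consistency, not field accuracy.

## Problem sizes and tolerances

The test suite exercises small fixtures for the exact oracles (≤ 300×300
morphology images, 8-row split enumerations) and one study-scale run
(39 × 39 frames) for the end-to-end recovery checks; geometric tolerances
are 1% for area and caliper-vs-sweep agreement, 2% for bent-chord
projection, 0.02 absolute for eccentricity, exactness for `Dev` and the
morphology/labelling/contour oracles. The acceptance script reruns the
study-scale pipeline in about ten minutes on one CPU.

## Known limitations

- The frame-level split inflates accuracy relative to unseen-animal
  deployment; use by-pig splits to size that gap.
- The correction stage learns the herd at hand; applied to a pig outside
  the training biometry range its boosted outputs saturate at leaf values.
- Perimeter and oblique rectangle sides carry the documented digitization
  biases; they are stable conventions, not unbiased physical measurements.
- The SVR/MLP/BP registry entries wrap third-party fits and are excluded
  from the portable JSON model dump.
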