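---
title: "How much data does a segmentation model need? Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How much data does a segmentation model need? Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicecast)
```

## The question and the approach

Supervised segmentation models in biomedical imaging are data-hungry, but
annotation is expensive and the marginal value of the next hundred labelled
scans is rarely known in advance. `dicecast` implements an empirical,
model-based answer in three stages:

1. **Learning curves.** A family of residual U-Nets, parameterized by
   depth (the number of encoder resolution levels), is trained on nested
   subsets of the training pool at a ladder of data ratios (for example 2%
   to 100% in 2% steps). Test-set Dice (DSC), IoU, recall and precision are
   recorded per (depth, ratio) cell, giving one learning curve per depth.
2. **Curve forecasting.** Lightweight recurrent forecasters (LSTMs) are
   trained on the observed *prefix* of each curve and predict the
   remainder, either one step at a time from actual history (one-step) or
   autoregressively from their own predictions (full-step). An ordinary
   least squares line serves as the baseline.
3. **Sufficiency estimates.** From an observed or forecast curve the
   package reports the plateau ratio — the point of diminishing returns —
   and the minimal data ratio that reaches a target Dice.

The package is self-contained: synthetic 2D (RGB, one bright deformed
blob) and 3D (4-channel, compact lesion) segmentation tasks and a
parametric curve simulator stand in for external datasets, so the entire
pipeline runs on a desk machine in minutes.

## The experiment grid

`ratio_ladder(start, stop, step)` builds the ratio ladder and insists that
the span is an exact multiple of the step; `training_grid()` crosses it
with the depth list (depth-major, ratio-ascending) and derives one
reproducible seed per cell from the base seed. Dataset splits use
largest-remainder apportionment, which reproduces classical 70/10/20
splits exactly (1000 samples give 700/100/200; 369 give 258/37/74).
Subsets at different ratios are **nested**: a single seeded permutation of
the training pool is drawn and subsets are its prefixes. Nesting makes
curves monotone-comparable — a larger subset strictly adds data rather
than resampling — and is one deliberate reading of "incremental subsets";
independently resampled subsets would only change the fluctuation
structure at small ratios.

## The segmenter family and its calibration

The architecture is a residual U-Net in which the computational mass sits
in the down/up-sampling transitions:

* a 3×3 stem convolution brings the input to `stem_width` channels at full
  resolution;
* each of the `depth − 1` encoder transitions is a *strided residual
  block* — 3×3 stride-2 convolution, BN, leaky ReLU, 3×3 convolution, BN,
  plus a strided 1×1 projection shortcut — doubling the channel count
  (`base_width * 2^level`) while halving resolution;
* the decoder mirrors it with 3×3 transposed convolutions and residual
  blocks applied to the concatenation with the skip feature;
* a 1×1 head with bias produces per-voxel foreground logits (sigmoid).

Convolutions carry no bias (BN follows each one); BN scale/shift count as
trainable parameters. Inputs must be divisible by `2^(depth − 1)`.
Convolution arithmetic runs in single precision through one whole-batch
im2col + GEMM per layer (roughly doubling single-core throughput);
parameters, optimizer state and normalization statistics stay in double
precision, so training remains bitwise reproducible on a given platform.

**Calibration.** The reference parameter counts for this family at depths
3–6 (6.0, 25.6, 103.9, ≈417 million) pin down the design more tightly
than one might expect. The count of any fixed per-level design grows like
`t·4^level`, and a systematic search shows that conventional
"block-then-pool" variants cannot reach a depth-4/depth-3 ratio above
about 4.15, while the reference ratio is 4.27. Concentrating parameters in
the strided transitions *and* giving the stem a width calibrated
separately from the stage base width closes the gap: with
`base_width = 109` and `stem_width = 97` (ratio ≈ 0.89) the family counts
6.007, 25.595, 103.932 and 417.25 million at depths 3–6 — matching the
reference values to one decimal in millions at depths 3–5 and continuing
the ≈×4 scaling at depth 6. Those widths are therefore the defaults of
`unet_spec()`; `unet_param_count()` computes counts from shapes without
allocating, and `count_parameters()` tallies a built model exactly.

Desk-scale experiments keep the same code path and shrink only the widths
via configuration (`base_width = stem_width = 4` by default).

Two small robustness choices matter at desk widths and do not change any
parameter count: activations are **leaky ReLU** (slope 0.1), because with
4-channel levels a single dead ReLU channel removes a quarter of a
layer's capacity and caused seed-dependent training stalls; and the head
bias is initialized to `qlogis(0.1)`, the logit of a typical foreground
prior, so early optimization works on localization rather than on
re-learning the base rate.

## Training engine

Training minimizes mean pixel-wise binary cross-entropy (computed from
logits in a numerically stable form) with Adam. After every epoch the
validation Dice (pooled, threshold 0.5) is evaluated; training stops when
it has not improved for `patience` epochs and the best-validation weights
are returned. A non-finite loss marks the cell as failed without stopping
the grid. All randomness (shuffling, initialization) derives from the
per-cell seed, so cells rerun identically.

API defaults (`default_hyper()`) are conservative: learning rate 1e-3,
batch 8 (2D) / 2 (3D), patience 10. The desk-scale pipeline profile
(`default_run_config()`) instead uses learning rate 1e-2, batch 16, 5
epochs, patience 3: at a 5-epoch budget and 1e-3 some seeds never leave
the all-background regime and their cells collapse to Dice 0, whereas
1e-2 converges within the budget across seeds. Metric aggregation is
pooled over test voxels (micro-average), which makes the identity
`dsc = 2·iou/(1 + iou)` exact on every record and is asserted in the
tests; per-image averaging is available via `aggregate = "per_image"`.

`run_grid()` appends one JSON record per completed cell and stores a hash
of the grid, so an interrupted run resumes from the last finished cell
and refuses to resume against a different grid.

## Synthetic tasks and the curve simulator

The 2D generator emulates endoscopy-like frames: a textured background
(sum of random low-frequency sinusoids), one bright, irregularly deformed
ellipse (polar radius modulated by 2nd–4th harmonics), additive Gaussian
noise. The `difficulty` level lowers contrast, softens the boundary and
raises noise. Blob radii are drawn so every mask's foreground fraction
stays within roughly 0.03–0.39. The 3D generator produces 4-channel
volumes with one compact deformed ellipsoidal lesion whose contrast
differs per channel (one channel is hypointense). What these fixtures do
*not* emulate: multiple lesions, class imbalance beyond the foreground
bounds, anatomical context, scanner artifacts — so a passing test suite
shows the pipeline's machinery is correct, not that full-scale Dice
values on clinical data would be reproduced.

The curve simulator draws from an exponential-saturation family
`D(r, d) = d_inf + depth_effect·(d − d_min) − (d_inf − d0)·exp(−r/τ)`
(clamped to [0, 1], plus observation noise). The family was chosen over an
inverse-power law in sample count because the ratio axis lives in (0, 1]
and empirical segmentation curves on a fixed pool visibly saturate; it is
a test fixture with a known closed form, not a scientific claim. The
closed form makes the plateau analytically invertible, which the tests
exploit: solving `D(1) − D(r) = ε` gives
`r* = −τ·ln(ε/(d_inf − d0) + e^{−1/τ})`. Defaults
(`d_inf 0.87, d0 0.4, τ 0.18, noise 0.01, depth_effect 0.02`) are chosen
once to resemble the range and spread of real segmentation learning curves.

## Forecasters

All four recurrent variants share one core: an LSTM (hidden size 64, one
layer) over sliding windows of `window = 5` curve points, each point a
normalized `(data ratio, log10 parameter count, Dice)` triple. Curves of
all depths are trained jointly — the parameter-count covariate lets one
model serve the whole family; a per-depth fit is a trivial restriction of
the input table. Training is full-batch Adam (lr 1e-2, 500 epochs) on the
squared error of the next Dice value, teacher-forced from the observed
prefix. The forecasting start point defaults to the 50% position.

Two numerical choices stabilize the autoregressive mode:

* **Monotone residual head.** The prediction is the window's last Dice
  input plus a softplus-constrained (nonnegative) increment. Learning
  curves are non-decreasing in expectation, and with a plain linear head
  the rollout's increments drift (down or up) once the ratio input leaves
  the observed range; the monotone head makes persistence the fallback
  and lets errors stay at the increment scale. The head bias starts at −3
  (softplus ≈ 0.05, the typical early-curve increment).
* **Causally smoothed inputs.** Dice *inputs* pass through a trailing
  moving average (width 3); targets are never smoothed. Teacher-forced
  training otherwise sees noisy windows while the rollout generates
  smooth ones; matching the two distributions removed a systematic
  rollout bias on noisy curves. Both choices are recorded here because
  they are where the design was genuinely open.

Bi-directional variants run a second LSTM over the reversed window. The
window never extends past the last observed (or previously predicted)
point, so no variant can read ground truth at or beyond the point it
forecasts — the tests enforce this with sentinel values. One-step and
full-step prediction agree exactly on the first forecast step by
construction. Predictions are clamped to [0, 1]. The linear baseline fits
`dsc ~ data_ratio` by OLS per curve prefix.

`evaluate_forecasters()` reports the mean absolute error of all points
after the prefix, per depth and overall, as mean ± population standard
deviation (the "mean ± std" table convention);
`forecast_evaluation_table()` renders the variants × (depths + Average)
layout.

## Sufficiency estimates

`estimate_plateau()` smooths the curve with a centered moving average
(width 3) and reports the smallest ladder ratio from which every smoothed
value stays within `epsilon` (default 0.01 Dice) of the smoothed
full-data value. The reference is the value at ratio 1.0, not the global
maximum, so a noisy spike cannot fake a plateau; no standard criterion
exists for "approximately 80%", so this rule is ours, configurable, and
labelled as such in reports. `minimal_data_for_target()` is the smallest
ladder ratio whose smoothed Dice reaches the target, `NA` when even full
data falls short. Estimates are reported on the ladder grid, never
interpolated — the protocol measures nothing between rungs, and
interpolation would imply precision it lacks. `sufficiency_report()`
pairs observed and forecast sources per depth and names the cheapest
(depth, ratio) combination meeting the target, preferring the shallower
depth on ties.

## Pipeline, caching, and problem sizes

`run_pipeline()` chains synth → grid → train → evaluate → forecast →
estimate. Each stage is keyed by a content hash of its configuration
slice plus its upstream keys; re-running an unchanged configuration
recomputes nothing and reproduces the identical manifest, while changing
e.g. only the target Dice recomputes only the estimate stage. The
manifest records the configuration, its hash, and every artifact path, so
any output can be re-derived from it.

The desk-scale defaults — 400 synthetic 64×64 images, depths {3, 4}, a
10%-step ladder, width-4 networks, 5 epochs — were chosen so a full
pipeline run takes a few minutes on one CPU core while still showing the
phenomena of interest: saturating, depth-ordered curves with small
fluctuations at low ratios, recoverable plateaus, and forecastable tails.
The acceptance checks run this configuration over three seeds and assert
only monotonicity in expectation (full-data Dice above 10%-data Dice per
depth), not absolute values: at this scale the absolute Dice of a width-4
network on synthetic blobs says nothing about clinical data.

## Known limitations

* The 3D path is exercised at small volumes (16³–32³) in tests; 128³
  patches are supported by the same code but are not desk-scale.
* The architecture calibration targets parameter counts only; FLOPs and
  inference throughput depend on counting conventions and hardware and
  are deliberately out of scope.
* Forecaster error estimates come from simulated curves; real learning
  curves can violate the monotone-in-expectation assumption (e.g. under
  divergence), in which case the monotone head will not track declines.
* Early stopping depends on a validation split; with no validation
  samples the final-epoch weights are returned.
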