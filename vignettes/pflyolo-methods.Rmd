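---
title: "PFL-YOLO in R: architecture, budgets and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PFL-YOLO in R: architecture, budgets and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pflyolo)
```

## The problem

Individual identification of livestock from face images is a small-object,
many-class detection problem: each image shows one animal's face, and the
detector must both localize the face and assign it to one of N identities
(N = 60 sheep in the motivating dataset). Deployment happens on phones and
embedded boxes, so the interesting regime is the trade-off between accuracy
and the parameter/FLOP/model-size budget. PFL-YOLO is a lightweight variant
of the YOLOv8n one-stage detector built from four substitutions:

* **EHConv** replaces the plain stride-2 convolutions: a grouped 3x3
  convolution, efficient channel attention (ECA), batch norm, and Hardswish,
  in that order.
* **RC2f** replaces the C2f stage: two stem convolutions (1x1 then grouped
  3x3), a four-way channel split with a Res2Net-style residual ladder
  (`y1 = x1`, `yi = Ti(xi + y(i-1))` for i = 2..4 with 3x3 transforms on the
  quarter width), concatenation, a 1x1 fuse, and ECA.
* **ESPPF** replaces SPPF: both 1x1 convolutions become grouped, and ECA is
  appended after the fuse.
* **PFDetect** replaces the decoupled detection head: per scale a grouped
  1x1 entry convolution, ECA, and a grouped 3x3 convolution with channel
  shuffle; the final 1x1 box and class projections are **shared across the
  three scales** (the "parameter fusion"). Box regression keeps the
  distribution-focal convention (`reg_max = 16` bins per side, decoded by
  expectation).

This package implements those blocks, assembles the 23-layer baseline and
every ablation variant from declarative graphs, counts parameters and FLOPs
per layer, and ships the dataset-curation and evaluation machinery around
them. The network engine (im2col convolutions, batch norm, pooling, ECA,
backprop) is written in base R; it is meant for desk-scale verification, not
production training.

## Counting conventions

Two conventions pin every number this package reports:

* **Parameters** are reported after folding batch norm into the convolution
  bias ("fused" counting): a BN convolution contributes
  `k^2 * Cin * Cout / g + Cout`. This is the convention under which the
  published per-layer budgets were evidently produced: the baseline head at
  60 classes counts 762,244 fused but 763,012 with the affine pair, and only
  the fused number matches the printed one -- exactly, not approximately.
  `count_params(..., fused = FALSE)` reports the affine-counted value, which
  is also what introspection of the instantiated weight arrays yields.
* **FLOPs** are `2 x` multiply-accumulates, convolutions only (including the
  fixed DFL projection and the tiny 1-D ECA kernel); pooling, upsampling,
  concatenation and activations are free. This convention reproduces the
  printed baseline head value 3.025 G at 640 px.

```{r budgets}
g_base <- build_baseline(nc = 60)
g_pfl  <- build_variant("all", nc = 60)
c(baseline = attr(count_params(g_base), "total"),
  pfl = attr(count_params(g_pfl), "total"))
c(baseline = attr(count_flops(g_base, 640), "total"),
  pfl = attr(count_flops(g_pfl, 640), "total")) / 1e9
```

## Calibrating the unstated group counts

The published description says *which* operations are grouped but never
prints the group counts or the head's internal width. Those free parameters
were recovered by a constraint search: the printed budgets for the baseline,
all eight ablation variants, the two heads (762,244 / 59,861 parameters and
3.025 / 0.405 GFLOPs) and the full-model totals (1.01 M / 3.3 G) define
parameter- and FLOP-windows at the printed precision, and block
configurations were enumerated until one satisfied every window
simultaneously. The frozen result, shipped as `pfl_default_config()`:

* EHConv groups per replaced layer (0, 1, 3, 5, 7, 16, 19) =
  (1, 16, 16, 16, 64, 64, 64) -- the stem layer has only 3 input channels
  and stays ungrouped.
* RC2f: hidden width = out-channels; 1x1 stem at g = 4; 3x3 stem at
  g = min(out/32, 4); ladder convolutions grouped (g = 2) only in the
  256-channel blocks; ungrouped fuse.
* ESPPF: g = 16 on both 1x1 convolutions.
* PFDetect: width 96; per-scale 1x1 entry convolutions at g = (8, 4, 2);
  per-scale ECA (k = 3); per-scale 3x3 at g = 8 with channel shuffle
  (8 groups); scale-shared box/class projections. This configuration counts
  **exactly** 59,861 fused parameters and 0.4047 GFLOPs at 640 px (printed:
  0.405).

Two structural questions the prose leaves open were settled by the same
arithmetic: RC2f must replace *all eight* C2f stages (neck-only substitution
cannot reach the printed 2.27 M row at a FLOP delta consistent with 7.0 G),
and the PFDetect projections must be shared across scales (per-scale
projections cannot reach 59,861 at any width/grouping consistent with
0.405 G).

The ECA kernel width follows the adaptive rule
`k = odd(floor((log2 C + 1) / 2))`, floored at 3 (so 3 for 16-128 channels,
5 for 256). Where a configured group count does not divide the channels of a
particular block instance, it is capped at the greatest common divisor.

## What the numbers mean

`size_estimate()` is `params x bytes / 1e6` plus a fixed 0.1 MB overhead for
checkpoint metadata; at fp16 the calibrated network gives 2.1 MB, the
baseline 6.1 MB, matching the printed sizes at their precision. Timing
statistics (`timing_stats()`) implement the mean-detection-time and
FPS = 1000/Dt definitions only; no hardware claims are made.

## Dataset curation

* **SSIM** (`ssim()`) is the single-window global-statistics form computed
  from image-wide means, variances (population denominators) and covariance
  with `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`. A tiled variant exists
  behind `windowed = TRUE` for robustness studies; the default is the form
  the curation procedure states.
* **Duplicate filtering** (`dedup_filter()`) is a greedy sequential scan in
  input order within each identity class: an image is dropped when its SSIM
  against any already-retained image of that class exceeds 0.75. The
  pairwise-comparison policy is not stated in the source description; the
  greedy reference-set scan is deterministic, idempotent, and seedless.
* **Split-then-augment** (`split_then_augment()`) partitions globally with
  `val = test = floor(N/10)` and augments afterwards, one copy per item
  within its own split. This is the only order/rule consistent with a
  6418 -> 5136/641/641 partition whose augmented splits are exactly doubled
  (augment-then-split would give floor(12836/10) = 1283, not 1282).
* **Augmentation** (`augment_once()`) draws exactly one of six transforms
  uniformly: horizontal flip, vertical flip, 90-degree rotation (k in 1..3),
  shift-scale-rotate, brightness/contrast, HSV jitter. Geometric transforms
  move the box by transforming its four corners and refitting the
  axis-aligned box (clipped, re-validated; degenerate results are redrawn).
  The shift/scale/rotation ranges are not printed in the source description;
  the defaults here are shift +/-6.25%, scale +/-10%, rotation +/-15
  degrees -- the conventional defaults of the augmentation library family
  the procedure names.

## Evaluation

Matching is greedy in descending confidence with one-to-one assignment at
the IoU threshold; AP integrates the monotone precision envelope exactly
(rectangle sum over recall steps), with a 101-point sampled variant behind
`method = "interp101"`; mAP@50:95 averages IoU thresholds 0.50 to 0.95 in
steps of 0.05. The confusion-count report defaults to confidence 0.25 and
IoU 0.5 (unstated in the source; these are the framework family's defaults).

The heatmap area of interest (`aoi_area()`) is: grayscale, normalize,
binarize (Otsu by default; a fixed threshold is available for reproducible
tests), fill interior holes, trace external contours, and sum their
Green's-theorem (shoelace) areas. The traced polygon runs through boundary
pixel centers, so a filled `w x h` rectangle measures `(w-1)(h-1)` and
non-rectangular regions yield half-pixel values; `method = "pixel"` counts
filled pixels instead (`w*h` for the same rectangle). Both conventions are
exercised in the tests.

## Synthetic data

`gen_face_dataset()` generates procedural stand-in faces: an ellipse with
two eye dots, a per-class hue from a golden-angle palette, and a per-class
stripe frequency/orientation, on a noisy background, with the ellipse's
bounding box as the single label. A configurable fraction of images are
near-duplicate jittered copies (SSIM > 0.75) to exercise the duplicate
filter. The generator emulates the *statistical structure* the pipeline
assumes -- one box per image, 60 separable identities, near-duplicate
frames -- and nothing about real barn imagery (occlusion, lighting, pose);
green pipeline tests therefore validate the machinery, not field accuracy.

## Smoke training

The production training recipe of the YOLOv8 family (task-aligned
assignment, CIoU + DFL losses, mosaic augmentation, EMA) is out of scope.
`smoke_train()` uses a deliberately minimal recipe: each target is assigned
to the single scale whose stride best matches its box size (about three
cells across) at the cell containing the box center; the loss is binary
cross-entropy on the class map (positive cells up-weighted 4x against the
~1:250 cell imbalance) plus a two-bin distribution-focal cross-entropy on
the box sides (unit weight); optimization is SGD with momentum 0.937,
lr 0.01 held for 60% of the run then decayed linearly to 10%, weight decay
5e-4 (the published optimizer settings, at smoke scale). Training runs at
64 px on 2 classes x 20 synthetic images for a few hundred SGD steps --
enough to overfit the training set to mAP@50 > 0.9 and
to give Grad-CAM a signal, and small enough for a CPU test suite. This
verifies that every block's forward/backward path is correct end to end; it
says nothing about full-scale accuracy.

Grad-CAM (`gradcam_map()`) backpropagates the best cell's class logit to a
feature layer, weights channels by spatially averaged gradients, and
rectifies. The default target layer follows the scale of the explained
detection (layers 15/18/21 feed the stride-8/16/32 heads): a layer off the
gradient path of the explained score receives zero gradient by construction
and would produce an empty map.

## Numerical choices and limitations

* Convolution uses im2col gathers with BLAS products; grouped convolutions
  loop over groups. Batch norm uses population batch statistics with
  momentum 0.03 running updates and eps 1e-5. Initialization is
  Kaiming-normal for convolution kernels, unit/zero BN affine, zero ECA
  kernels (every channel weight starts at sigmoid(0) = 0.5); every entry
  point takes an explicit seed.
* Backward passes are verified against central finite differences at small
  sizes (relative error around 1e-8); forward-equivalence tests use a
  max-abs tolerance of 1e-5 in keeping with 32-bit practice, though R
  computes in doubles.
* Problem sizes in the tests (64-96 px images, 2-60 classes, tens of
  images, a few hundred training iterations) are desk-scale choices: the
  package targets architecture arithmetic and pipeline correctness, for
  which these sizes are sufficient and fast.
* Hardswish as printed has its minimum -0.375 at x = -1.5 (it is not
  monotone from -3); ECA's zero-padded 1-D kernel gives edge channels a
  truncated support, so "equal channels get equal weights" holds for
  interior channels.
* The calibrated configuration reproduces every printed budget at its
  printed precision, but it is a solution consistent with those budgets,
  not a disclosure by the original authors; other configurations inside the
  same rounding windows exist, and all acceptance figures are reported from
  the shipped configuration.
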