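---
title: "Segmentation-guided ROI preprocessing for jaw-lesion classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-guided ROI preprocessing for jaw-lesion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionroi)
```

## The question the package addresses

Differentiating ameloblastoma (AME) from odontogenic keratocyst (OKC) on
axial slices of volumetric dental imaging is a two-class problem whose
discriminative evidence is concentrated at the lesion and its bone
interface: AME is preferentially multilocular with internal septa and a
scalloped, corticated margin, OKC preferentially unilocular with smooth
margins and more frequent cortical disruption. When a classifier is fed the
full axial slice it must find this evidence among distractors (spine,
airway, soft tissue); segmentation-guided preprocessing instead hands the
model a region of interest derived from a lesion mask.

The package implements the complete comparative loop for four input
variants:

* **original** — the untouched axial slice;
* **bbox** — a mask-centered square crop, side grown by 20%;
* **precise** — the same crop with every pixel outside the segmentation
  mask zeroed;
* **expanded** — the crop masked with a morphologically dilated mask
  (default margin 3 mm), which keeps a band of bone-lesion interface.

The working hypothesis is an ordering: masking out background helps
(anything beats the original slice), but masking *too tightly* discards
interface anchors, so the moderately expanded ROI should be the best of the
three segmentation-guided inputs.

## The phantom cohort

No imaging data ship with the package; a synthetic phantom cohort
([`cohort_config()`], [`generate_cohort()`]) provides volumes whose
statistical structure matches the study design the pipeline assumes.

Each patient is a 3D intensity volume (arbitrary units in [0, 1000],
voxel size 0.3 mm by default) containing:

* a **lucent cavity**: one ellipsoid (unilocular) or a chain of 2-4
  overlapping ellipsoids (multilocular), equivalent radius drawn uniformly
  from 6-15 mm; chained placement keeps the centers closer than the sum of
  the minimal semi-axes, so the cavity is always one connected component;
* **septa**: high-intensity bony walls where the boundary shells of two
  locules intersect (band 0.88-1.04 in normalized-radius units, millimeter
  scale at the default radii), plus bony crease spurs at the inter-locule
  notches of the margin;
* a **corticated rim** following the traced boundary from the outside.
  Rim *smoothness* is a class feature: unilocular lesions wear a ring of
  constant thickness, multilocular lesions a scalloped ring whose thickness
  oscillates with the in-plane azimuth, plus bony crease spurs at the
  inter-locule notches (thickness oscillating between 0.02 and 0.22
  normalized-radius units at 5-9 cycles per revolution). A disrupted
  cortex removes the rim inside a random cone;
* **distractors**: 2-4 bright ellipsoids placed away from the lesion by the
  same law for both classes, emulating spine/airway attention sinks;
* additive Gaussian noise (SD 20 units).

Class identity enters *only* through the per-class probabilities of three
radiographic features — multilocularity (0.766 AME / 0.281 OKC), cortical
disruption (0.281 / 0.516), septa (tied to locularity) — taken from the
observed cohort frequencies. Background and distractor distributions are
identical across classes, so a classifier can only beat chance by reading
the lesion and its interface.

### The segmentation mask is a tracing, not the cavity

The stored `LesionMask` is deliberately *not* the voxel-exact cavity: it is
a smooth-min envelope of the locule union (temperature `trace_smoothness`,
default 0.22 in normalized-radius units) that rounds the inter-locule crease notches, the
way a human contour follows the overall lesion boundary rather than every
bony crease. For unilocular lesions the tracing equals the cavity. The tracing covers
*lesion tissue only*: bony septal walls are bone, not lesion, so they are
excluded from the mask (a largest-connected-component guard keeps the
tracing a single region), and all interface structure — the scalloped or
smooth rim, the crease spurs — lies strictly outside it. This is the
geometric fact that makes the ROI-ordering hypothesis testable: the precise
variant (mask-out with the tracing) excludes the septal walls and the
interface band, while the expanded variant (mask-out with the 3 mm-dilated
tracing) recovers them.

### What the phantom does not emulate

No beam hardening, metal or motion artifacts, no teeth or roots, no
anatomy-dependent background texture, no segmentation error beyond the
smooth tracing, and lesion sizes are drawn from a declared uniform range
because the study reports no size distribution. Passing tests on the
phantom therefore show that the *pipeline logic* behaves as designed
(leak-free partitioning, correct weighting, correct metrics, the interface
mechanism of the ROI ordering); they do not certify clinical performance on
real scans.

## Preprocessing

Slice selection ([`select_slices()`]) computes the per-slice lesion area
along the axial (third) axis, keeps slices with area strictly greater than
50% of the maximum, and takes every 5th retained slice, anchored at the
first; the maximum-area slice always survives. The strict inequality, the
anchor, and the filter-before-stride order are fixed conventions; indices
are 1-based throughout the package.

The square crop ([`bbox_square_roi()`]) has side
`ceiling(1.2 * max(bbox_height, bbox_width))` centered on the bounding-box
center; out-of-image regions are zero-padded so the lesion stays centered.
The 20% growth is interpreted as total side growth (x1.2), not per side.
Dilation ([`dilate_mask()`]) uses the Euclidean digital disk with pixel
radius `round(margin_mm / in-plane spacing)`; the default margin of 3 mm
covers a bone-interface band a few voxels wide at 0.2-0.3 mm resolution.

## MAPS sampling

Mode-Adaptive Patient-Centric Sampling decouples the two places where
per-patient slice counts can bias an experiment. For **training**,
patient `p` with `N_p` images gets weight `W_p = min(N_p / N_bar, 2)`
(`N_bar` the mean image count); patients are drawn with replacement
proportional to `W_p` and one of their images uniformly — so prolific
patients cannot dominate an epoch (cap at 2) and sparse patients are not
oversampled (ratio below the cap). The hierarchical patient-first scheme is
the default because it makes the cap meaningful at the patient level; a
flat per-image weighting with `W_p / N_p` is available
(`training_sampler(level = "image")`) and has the same expected per-image
draw probability. For **evaluation**, every patient is visited exactly once
per pass and all their slices are emitted contiguously, so each case
contributes once to patient-level metrics. One training epoch makes
`N_total` draws.

## Classifier backend

The default backend ([`cnn_backend()`]) is a compact 4-block CNN at 64x64:
3x3 convolutions (8/16/32/32 channels), each followed by batch
normalization and ReLU, 2x2 max pooling after the first three blocks,
global average pooling, and a 32/16 dense head ending in a 2-way softmax.
Training uses AdamW (decoupled weight decay 1e-4) with the two-phase
learning-rate schedule: linear warm-up, cosine decay to a floor, a hard
reset at a configurable epoch, and a second cosine decay. Augmentation in
training mode applies random horizontal flips (p = 0.5), rotations within
±15°, translations within ±5% and scaling within 95-105%, with intensities
normalized to [0, 1]; evaluation mode only resizes and normalizes.

Two deliberate departures from a transfer-learning setup are documented
here because the backend trains *from scratch* at desk scale:

* the dropout ladder keeps its descending structure but defaults to
  0.3/0.2/0.1. Rates of 0.6-0.3 are appropriate for a 2048-feature
  pretrained head; on this backend's 32-unit head they prevent any learning
  at realistic epoch budgets.
* batch normalization in every convolution block is what makes a
  from-scratch CNN learn under full augmentation within tens of epochs;
  inference uses running statistics (momentum 0.1).

The backend is a contract ([`train_backend()`], [`predict_proba()`],
[`feature_grads()`]), not a fixed architecture: any model exposing these
three generics — including a large pretrained network — can be plugged into
the same experiment.

Numerical notes: convolutions are evaluated as im2col gathers feeding BLAS
matrix products with C++ kernels for the gathers, pooling and batch-norm
column statistics; gradients of every layer are verified against finite
differences in the test suite; max-pooling ties resolve to the first
element in column-major order; an all-zero Grad-CAM map is left at zero
rather than divided by zero.

## Evaluation

Cross-validation partitions *patients*, never slices
([`partition_patients()`]): stratified fold assignment keeps per-stratum
and total fold sizes within one, and [`train_backend()`] refuses outright
to fit when a patient appears on both sides of a split — data leakage is a
hard error, not a warning. Within [`cross_validate()`] the held-out fold
doubles as the early-stopping validation set, mirroring a k-fold protocol
with per-fold monitoring.

Metrics follow the standard confusion-matrix definitions with AME as the
positive class; specificity is `TN / (TN + FP)` (the quantity whose
complement is the ROC false-positive axis). Undefined ratios are reported
as `NA` with a warning. Patient-level predictions average slice
probabilities (soft voting); a mean of exactly 0.5 classifies as AME, a
fixed documented tie rule with a configurable threshold.

AUC is the midrank Mann-Whitney statistic; its variance and the paired
test for two correlated ROC curves use DeLong's structural-components
method, cross-checked in the suite against brute-force pair counting, a
permutation oracle, and the independent pROC implementation. Cohort
characteristic tables use Pearson's chi-square *without* continuity
correction — the form that reproduces the printed cohort p-values — and the
Mann-Whitney U test with the exact distribution when the smaller sample has
fewer than 20 observations.

The one-command experiment ([`run_experiment()`]) trains all variants on
the same slice selection, the same folds and the same seeds, and reports
per-variant metrics at both levels plus pairwise DeLong p-value matrices on
pooled out-of-fold predictions, which are paired across variants by
construction.

## Interpretability

Grad-CAM ([`grad_cam()`]) weights the final convolution block's activation
maps by the spatially pooled gradient of the target-class logit, rectifies,
bilinearly upsamples to the input size, and min-max normalizes; the map is
invariant to positive rescaling of the gradients. Confidence curves
([`confidence_curve()`]) trace a patient's slice probabilities in slice
order; the *population* SD over the patient's slices (the slice set is the
whole population for that patient) drives low-confidence flagging, with
declared defaults: SD above 0.15, or mean within 0.1 of the 0.5 decision
line. Both cutoffs are configurable; they are design defaults, not
estimated quantities.

## Problem sizes

Unit tests run on miniature volumes (about 48 voxels per side, 2-20
patients). The comparative experiment in the acceptance material uses a
40-patient cohort at the default volume geometry, three folds, and a
12-epoch schedule with the phase-2 reset at epoch 10 — sizes chosen so the
full four-variant experiment is a desk-scale computation while still
exercising every stage of the pipeline, including the learning-rate reset.

## Known limitations

* The phantom's class signal is geometric and intensity-coded; it has no
  patient covariates (age, sex, location), so the cohort-table statistics
  are exercised on published count tables rather than generated metadata.
* The default backend is a small from-scratch CNN; absolute AUCs on the
  phantom are not comparable to fine-tuned large-network results on real
  data — only the *ordering* of input variants under identical training is
  the object of study.
* DeLong's test assumes asymptotic normality of the AUC difference; at a
  handful of patients per fold its p-values are indicative only (the suite
  checks its calibration against a permutation oracle at realistic sizes).
* Confidence-curve flagging thresholds are declared defaults; calibrating
  them would require real reader studies.
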