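---
title: "Foveal 3D segmentation of lymph-node-like lesions in CT: models and methods"
author: "fovealCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal 3D segmentation of lymph-node-like lesions in CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovealCT)
```

## The problem

Staging of nodal disease in oncology relies on finding and measuring
lymph nodes in contrast-enhanced CT of the thorax.  Manual whole-volume
segmentation of every node is prohibitively slow (dozens of nodes per
scan), so fovealCT implements a fully automatic pipeline: a 3D fully
convolutional *foveal* network (f-net) produces a per-voxel lesion
probability map for a whole CT volume, the map is thresholded, and the
resulting binary mask is decomposed into connected components that stand
for individual detected nodes.  Evaluation is component-level: a
ground-truth node counts as detected when at least one of its voxels is
covered by any predicted component, a predicted component without any
ground-truth overlap is a false positive (FP), and segmentation quality
is judged on Dice/TPR/PPV after removing missed nodes and FPs from the
masks.  This deliberately loose detection criterion reflects clinical
reality: adjacent nodes merge into clusters, and one-to-one
correspondence between predicted and true components is often
impossible.

## The foveal network

Unlike a u-net, which ingests a single-scale image and builds coarser
scales internally, the f-net receives its multiscale context explicitly:
each training sample is a pyramid of `L` co-centered patches with
identical voxel dimensions, where level `l` covers `2^(l-1)` times the
physical extent of the finest level (an octave pyramid, mimicking the
retina's high acuity at the fovea and coarse acuity in the periphery).
Each level enters its own *feature-extraction pathway* of CBR blocks —
valid (unpadded) 3x3x3 convolution, batch normalization, ReLU.  With
`B` blocks, every pathway maps a patch of `P` voxels per edge to
`P - 2B` voxels (each valid 3^3 convolution removes one voxel per
side).

The pathway outputs are then merged coarse-to-fine in a *feature
integration pathway*: the coarser integration output is upsampled by the
pyramid factor (nearest-neighbor by default), both inputs are
center-cropped to their common valid region, concatenated along
channels, and passed through one integration CBR block.  After the
finest level is merged, a 1x1x1 projection and a channel-wise softmax
yield pseudo-probabilities for background and lesion at every voxel of
the valid-output region.  `fnetShapes()` exposes the exact output size
and its offset inside the finest patch; for the reference configuration
(4 levels, 3 blocks, 32^3 patches) the output is 24^3 with offset 4.

Decisions that the architecture description leaves open, and how this
package resolves them:

* **Integration operator.** Upsample, center-crop to align valid
  regions, concatenate, then one CBR block (the "CBRU" ordering).
  Crop offsets use `floor((larger - smaller)/2)`, so odd differences
  shift by half a voxel; with even patch sizes all crops are symmetric.
* **Channel widths.** Defaults (16, 32, 64) per pathway and 32 for
  integration; all configurable.
* **Upsampling.** Nearest-neighbor by default (cheap and free of
  checkerboard artifacts); trilinear available.
* **Output resolution.** A single finest-resolution output head; no
  deep supervision.
* **Batch normalization.** Standard running mean/variance with momentum
  0.1 and eps 1e-5, frozen in evaluation mode.

The network, its backward pass and the AdaDelta optimizer are
implemented in the package itself (R with C++ kernels for the valid 3D
convolutions via im2col/GEMM); gradients are verified against finite
differences in the test suite.

## Preprocessing

Volumes are resampled to a fixed isotropic grid of 1.5 mm spacing
(trilinear for intensities, nearest for label masks, output shape
`round(n * spacing / 1.5)` per axis with round-half-away-from-zero,
minimum one voxel).  Intensities are clipped to the soft-tissue window
750/70 HU — read as width 750, level 70, i.e. `[-305, 445]` HU; the
constructor takes explicit `level` and `width` arguments, so the
opposite reading is one keyword away.  The window can also be estimated
from data: `estimateWindow()` computes the mean and standard deviation
of all labeled voxels together with their direct neighborhood (box
dilation of 1 voxel, i.e. the 26-connected shell) and maps them as
`level = mean`, `width = 2 * k * sd`.  The default `k = 3` makes
node-like voxels spread around 70 HU with sd 125 HU reproduce 750/70;
both the dilation radius and `k` are exposed because the mean/sd-to-
window mapping is a convention, not a unique truth.  Network inputs are
finally rescaled linearly so the window spans `[-1, 1]`; out-of-volume
patch samples are padded with the lower clamp (-1), mimicking clipped
background.

## Training

Training draws random patch pyramids from the preprocessed volumes.  At
least 30% of each epoch's patches are guaranteed to contain lesion
voxels: those centers are jittered around randomly chosen foreground
voxels (the jitter keeps the voxel inside the valid-output region), the
rest are uniform over the volume.  Each patch is augmented on the fly
with one random similarity transform — scale uniform in
`[1/1.1, 1.1]`, rotation up to 7 degrees about a uniformly random 3D
axis — folded directly into the pyramid's sampling grid, so no border
information is lost; labels use the identical transform with
nearest-neighbor sampling, which cannot invent new node ids.  Stronger
augmentation is deliberately not offered.

The loss is the voxel-wise cross-entropy (probabilities clamped at 1e-7
for finiteness; optional class weights, off by default — foreground
prevalence is controlled by the sampling rule instead).  Optimization
uses AdaDelta with rho 0.95 and eps 1e-6, minibatch 8.  An "epoch" is
`patchesPerEpoch` freshly drawn patches (default 100); the reference
schedule of 1000 epochs is a GPU-scale setting, and the package default
of 50 epochs is a desk-scale choice.  `makeCVFolds()` provides the
randomized balanced fourfold split used for cross-validation.  All
randomness — phantom generation, initialization, sampling, augmentation,
minibatch order — derives from explicit integer seeds, and training runs
are bit-reproducible.

After training, the operating probability threshold is selected by
exhaustive grid search over `0.05, 0.10, ..., 0.95`: for each value the
mean foreground Dice over the training volumes is computed and the
maximizer returned, ties broken toward the lowest value (an empty
prediction against an empty ground truth counts as Dice 1).  Whether to
optimize per cross-validation fold or once globally is left to the
caller; `optimizeThreshold()` operates on whatever dataset it is given,
global by default.  The fixed threshold 0.4 is the published operating
point and the package default at inference.

## Inference

`predictVolume()` tiles the volume so that the valid-output regions of
the patch pyramid cover every voxel; overlapping predictions are
averaged (smooth seams, deterministic).  Because the network is fully
convolutional, inference may use a larger patch than training to cut
tiling overhead.  `segmentProbability()` binarizes the foreground
probability at the threshold, with `>=` (boundary inclusive — the
comparison direction is a documented convention).  Connected components
use 26-connectivity by default (6 and 18 available), ids in scan order,
and no minimum-size filter by default, so FP counts are reported
unfiltered; a `minComponentVoxels` option exists.

## Evaluation protocol

`evaluateDetection()` reproduces the component-level protocol: per-node
detected flags (any-overlap), per-volume FP counts, the detection rate
(detected/total), mean FP per volume, matched-mask Dice/TPR/PPV per
volume (undefined when nothing was detected — such volumes return NA and
are excluded from means, with the count reported), and detection rates
stratified by short-axis diameter (SAD) into half-open groups
`[5,10)`, `[10,20)`, `[20,Inf)` mm; nodes under 5 mm are excluded from
evaluation.  The group boundary convention is documented and
configurable because prose mixing ">10" and ">=10" is ambiguous.
Bootstrap variability of a detection rate resamples the per-node flags
with replacement at full sample size (default 10,000 resamples,
seeded).  Rate comparisons use a two-sided unpaired Welch t-test on the
per-node 0/1 indicators; Welch is chosen over Student since group
variances differ, and the per-node (rather than per-patient) unit is
the default while per-patient rates can be passed just as well.

SAD of a component is estimated as the minimal caliper width of the
in-plane convex hull on the axial slice of maximal cross-sectional
area, with voxel centers expanded to their in-plane corners (so a
single voxel has SAD equal to the spacing).  This is a design choice —
clinical SADs come from annotation tools — and ground-truth SADs from a
node table override computed ones whenever provided.

## The phantom generator

All tests and the acceptance script run on synthetic phantoms
(`generatePhantom()`): Gaussian soft-tissue background (20 +/- 15 HU),
ellipsoidal lesions at 70 HU — the soft-tissue window level, which makes
the window-estimation check meaningful — with axis ratios in
`[1, 1.6]` and the short axis in-plane, so the drawn SAD is the
in-plane short-axis diameter and genuinely exercises the caliper
estimator; bright straight tubular vessels (250 HU) as confounders;
additive Gaussian noise applied last.  Lesions are placed with a
one-voxel guard band (unless cluster mode merges several ellipsoids
under one id to emulate bulky disease), and placement failure after a
bounded number of attempts is an error reporting the achieved count.
One global seed drives a fixed stream order (background, per-lesion
geometry, vessels, noise), so phantoms are bit-reproducible.

What the phantom does *not* emulate: anatomy (mediastinal geometry,
station structure), intensity inhomogeneity, partial-volume and beam-
hardening artifacts, contrast-phase variation, and the extreme
foreground sparsity of clinical scans.  Passing the end-to-end checks
therefore demonstrates that the implementation learns and evaluates
correctly, not that the published clinical detection rates transfer;
those were obtained on 89 clinical scans after GPU-scale training and
are out of scope here.

## Desk-scale problem sizes

The test suite and the acceptance script train a reduced configuration
chosen as the package's study condition for synthetic data: two levels,
two CBR blocks of 8 channels per pathway, 16^3 training patches, 50
epochs of 64 patches with minibatch 8, on twelve 64^3 phantoms, with
threshold selection on four of them and inference at 40^3 patches.
The schedule length matters mainly for false positives: vessels are
rare in the sampled patches, so short schedules leave confident
vessel-shaped false detections that the longer schedule suppresses.
On these high-contrast phantoms this schedule reaches held-out
detection rates of 1.0 for lesions with SAD >= 10 mm in most seeds with
few false positives per volume; the end-to-end acceptance test requires
rate >= 0.8 and FP <= 5 in at least 8 of 10 seeds.  The reference
4-level, 32^3-patch configuration remains the default for
`fnetConfig()` and is exercised structurally (shape contracts, gradient
checks, forward determinism) rather than trained to convergence.

## Numerical choices and degenerate inputs

* Probability clamping at 1e-7 inside the cross-entropy keeps the loss
  finite; batch-norm eps is 1e-5.
* `round(n * s / t)` uses round-half-away-from-zero so resampled shapes
  do not depend on banker's rounding; outputs never drop below one
  voxel.
* Resampling clamps sample positions to the grid edge; pyramid and
  augmentation sampling pad with an explicit value instead (labels pad
  with background 0).
* Empty masks: `estimateWindow()` and lesion-constrained sampling raise
  errors; empty components are rejected by `sadOfComponent()`.
* Both-empty reduced masks yield NA segmentation metrics; zero-variance
  rate comparisons return p = 1 for equal means and NA (with a warning)
  otherwise.
* Ties: threshold selection returns the lowest optimal grid value; the
  max-area axial slice for SAD takes the lowest slice.

## Known limitations

* The f-net here is a faithful but compact reimplementation; it has no
  GPU path, so the published 1000-epoch schedule on clinical volumes is
  impractical — the architecture, losses and evaluation are what the
  package validates.
* MetaImage support covers uncompressed scalar 3D images only.
* Axis orientation is assumed aligned with the world frame (no
  direction cosines); DICOM series reading is out of scope.
* Station labels are pass-through metadata; no station geometry is
  modeled.
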