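---
title: "spinequant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinequant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spinequant quantifies dendritic spines and dendrites in 3D fluorescence
microscopy z-stacks. This vignette explains the models the package
implements, the parameters that matter, the synthetic data that makes the
pipeline testable without external data, and the design decisions taken
where the problem was genuinely open.

## The segmentation model

Spines and dendrites are segmented by a dual-decoder convolutional network.
A shared encoder condenses a single-channel tile (intensities normalized to
[-1, 1]) through `D` stages of residual blocks and 2x2 max-pooling into a
latent representation; two structurally identical decoders — one per target
class — reconstruct full-resolution probability maps from that latent space,
each decoder stage consisting of parameter-free 2x nearest-neighbor
upsampling, concatenation of the matching-scale encoder features (skip
connections), and an ordinary 3x3 convolution. Upsampling + convolution is
used instead of transposed convolution to avoid checkerboard artifacts.
Batch normalization precedes every activation; all activations are the
swish function `x * logistic(x)` except the final 1x1 convolution of each
head, which applies the logistic `1 / (1 + exp(-x))` so outputs are
probabilities in [0, 1]. Capacity is controlled by the initial filter count
`F` (8, 16 or 32; filters double at each stage) and the depth `D`
(default 4). Splitting the decoders rather than emitting two channels from
one decoder lets each class develop its own reconstruction pathway while
sharing low-level features; zeroing one decoder's weights provably leaves
the other head's output unchanged (tested).

Two asymmetric losses reflect the asymmetric targets: dendrites are
extended, connected structures for which the overlap-based Dice loss
`1 - 2*sum(y*yhat) / (sum(yhat^2) + sum(y^2))` is well suited; spines are
small and sparse, and are optimized with pixel-mean squared error, which
behaves better than Dice for tiny structures. The two losses are kept
separate per head — by default their gradients are summed into one update
with unit weights; a configuration switch (`loss_mode = "alternate"`)
instead alternates strictly between per-loss updates. Both satisfy the
design requirement that the losses are never collapsed into a single
blended objective; the summed form is the default because it is stabler in
small-batch regimes. The Dice denominator carries an epsilon of 1e-7 so
empty tiles are well defined (two empty maps give loss 0). The MSE uses a
mean (not sum) reduction so the loss is invariant to tile size.

A note on the activation definitions: the logistic is implemented in its
standard form `1/(1 + exp(-x))`. A sign variant with a minus in the
denominator has a pole at 0 and cannot produce probabilities, so it cannot
be what a probability-output layer uses; the standard form is the only
self-consistent choice.

The network, batch normalization, pooling/upsampling, backpropagation and
the Adam optimizer are implemented directly in R on top of BLAS matrix
multiplication (im2col convolutions). The backward pass is verified against
central finite differences for every parameter tensor in the test suite
(worst relative error on the order of 1e-5), which is the strongest
correctness guarantee available for hand-written backpropagation.

## Training

Training streams random tiles (default 128 px square, configurable) from
annotated stacks: a random window from a random plane of a random stack,
sampled uniformly — there is no foreground-biased sampling. Image tiles are
linearly normalized per tile so the minimum maps to -1 and the maximum to
+1 (constant tiles map to 0); at inference the same normalization is
applied per plane. Augmentation applies geometric transforms (horizontal /
vertical flips, 90-degree rotations, small rotations in [-10, 10] degrees)
identically to the image and both masks — masks use nearest-neighbor
interpolation and are re-binarized at 0.5 — and photometric transforms
(Gaussian noise, brightness, contrast) to the image only.

The learning rate starts at 5e-4, is held for 15 warm-up epochs, and then
decays as `exp(-0.1 * (epoch - 15))`. The decay constant is interpreted as
a per-epoch multiplicative rate: a literal time constant of 0.1 epochs
would collapse the learning rate to ~0 within a single epoch, which cannot
be a usable schedule. Two resolution regimes are supported: `fixed` rescales
every stack to a common working resolution (conventionally 94 nm/px) before
windowing; `mixed` samples tiles at each stack's native resolution, which
improves robustness when inference data departs from the training
resolution. Stacks smaller than the tile are reflect-padded. Since
streaming has no natural epoch, an epoch is simply `steps_per_epoch`
optimization steps, a configuration value.

Batch size (32) and epoch count (50) defaults are configuration values, not
claims about any reference training run; the scaled-down validation runs in
this package use tile 32-48 px, batch 8, and a few hundred Adam steps at a
constant 2e-3 learning rate, sizes chosen so that the full train/predict/
evaluate cycle runs comfortably on a single desktop CPU core.

## Inference and post-processing

Prediction is plane-separable: each z-plane is normalized, reflect-padded to
a multiple of `2^D` (reflect rather than zero padding avoids border ramps),
pushed through the network in evaluation mode (batch-norm running
statistics; bit-reproducible), and cropped back. Optionally the stack is
first rescaled to the model's working resolution and the maps are rescaled
back.

Post-processing first cleans the dendrite map: binarize at 0.5, remove
per-plane (2D, 8-connected) components below `min_size_2d` (default 10 px)
and volumetric (3D, 26-connected) components below `min_size_3d` (default
50 voxels). It then gates the spine map: the cleaned dendrite mask is
dilated by a physical radius (default 1 um; the structuring element is an
ellipsoid in voxel units, i.e. a sphere in micrometers under anisotropic
voxels) and spine probability outside the dilated mask is zeroed — an
implicit maximum distance-to-dendrite criterion. All sizes/thresholds are
configuration values; connectivity (26-neighborhood in 3D, 8 in 2D) is
documented and configurable. Cleaning + gating is idempotent (tested).

## ROI building

Two builders convert the spine probability map into discrete 3D ROIs:

* **Flood fill** — seeds are unvisited voxels above `seed_threshold`
  (default 0.25), taken in decreasing probability order with deterministic
  tie-breaking. A region grows over 26-connected neighbors whose
  probability is at least `rho` times the seed probability (default
  `rho = 0.5`; "relation to seed" is interpreted as this relative floor)
  and whose physical distance to the seed is at most
  `max_distance_to_seed_um` (default 3 um). Visited voxels are never
  reused, so ROIs partition their support.
* **Connected components** — binarize at `area_threshold` (default 0.25)
  and label 3D 26-connected components.

Native 3D growth is the default; a per-plane 2D mode is obtained by running
the same algorithms on single-plane stacks. Acceptance filters keep an ROI
iff its voxel count lies within `[min_roi_size_vox, max_roi_size_vox]`
(defaults 10 and 10,000), it spans at least `min_planes` z-planes, and —
when an explicit distance bound is configured instead of the implicit
dilation gate — its minimum physical distance to the dendrite mask is below
the bound. Both builders are verified voxel-for-voxel against independent
brute-force implementations on small random maps. Note on `min_planes`:
with strongly anisotropic voxels (e.g. 0.5 um z-steps) a true spine head of
0.3 um radius can occupy a single plane, so the synthetic validation runs
use `min_planes = 1`; the default of 2 reflects the finer-grained maps of
typical real acquisitions, where a spine smeared by the axial PSF spans
several planes.

## Multi-rater annotation clustering and reliability

Point annotations of spine centers from several raters (an algorithm's ROI
centroids can join as an extra rater) are matched by density clustering.
Coordinates are scaled anisotropically so the xy radius (0.85 um) and z
radius (2.5 um) become one common radius; clustering then takes the
connected components of the eps-neighborhood graph with every point a core
point — exactly DBSCAN with `min_samples = 1`. The minimum cluster size must
be 1 because spines found by a single rater are a meaningful category of
the analysis; no annotation may vanish. The published radii drive three
adjustment passes: (i) members farther than the radii from their cluster
centroid are ejected into singleton clusters (farthest first, centroid
recomputed after each ejection); (ii) clusters with more than 7 members
(7 = number of raters) are split by 2-means — initialized with the two most
mutually distant members under a fixed seed — until none is oversize;
(iii) cluster pairs whose centroids lie within the radii are merged
greedily (nearest first) provided the merged cluster stays within the size
bound *and* every member remains within the radii of the merged centroid.
The extra membership condition on merges is needed to keep the documented
cluster invariant (all members within the radii) true unconditionally;
without it a merge could silently violate the radii. Whether one cluster
may hold two annotations of the same rater is left open in the source
procedure; it is allowed here, and recall counts each rater once per
cluster.

Pairwise recall between raters A and B is the fraction of A's clusters that
also contain B; inter-rater reliability (IRR) is the mean +/- sd of the
off-diagonal recall matrix. Intra-rater reliability across two annotation
rounds is computed by re-clustering each rater's own two rounds in
isolation (maximum cluster size 2) — pooling all raters' two rounds into
one clustering would saturate the 7-member cap with 14 annotations per
spine and corrupt the statistic. Pixel-level agreement uses IoU, with the
convention that two empty masks have IoU 1 (perfect agreement on absence).

Because the exact density-clustering hyperparameters behind the published
benchmark statistics are not reported, reproduced reliability values on
that benchmark may shift by a percentage point or two; the implementation
fixes `eps = r_xy` after anisotropic scaling, which reproduces the stated
radii semantics exactly.

## Fluorescence quantification

ROI traces are the mean raw fluorescence over an ROI's voxels per movie
frame (linear in the movie; tested). Calcium activity is expressed as
`dF/F0 = (F - F0)/F0` with `F0` the mean over user-chosen baseline frames
(conventionally ~20 frames free of spontaneous events; choosing them is an
expert judgment, so the indices are explicit arguments — an optional
lowest-rolling-mean heuristic exists but is off by default). The
ratiometric spine-to-dendrite ratio compares a maturity marker (e.g. a
tagged PSD-95 nanobody) to a structural marker:
`RSDR = (M_spine/S_spine) / (M_dendrite/S_dendrite)`, with the dendrite
reference taken over all dendrite-labeled voxels in the field of view.
RSDR > 1 indicates preferential spine localization; the ratio is invariant
to global gain in either channel. Trace agreement between automatic and
manual ROIs uses Pearson correlation, optionally after a centered 9-point
moving average with edge truncation (shorter windows at the boundaries).

## Synthetic data: what it emulates and what it does not

The generator builds scenes of smooth tubular dendrites (random quadratic
Bezier curves rasterized as capsule chains) with spines attached by thin
necks (neck capsule + head sphere; necks are labeled as spine, keeping the
two label masks disjoint, which simplifies the loss targets). Defaults
mirror a typical ex vivo two-photon acquisition of CA1 pyramidal dendrites:
94 x 94 x 500 nm voxels, 0.5 um dendrite radius, head radii 0.25-0.4 um,
neck lengths 0.3-0.8 um, PSF sigma (0.1, 0.1, 0.35) um, background 10 and
structure amplitude 100 intensity units with Gaussian read noise (sd 3) and
shot-like noise with intensity-proportional variance (scale 0.4 — the
Gaussian approximation to Poisson noise shares its first two moments and is
much faster at desk scale; exact Poisson sampling is not required for any
statistic used here). Head-to-head separation greater than twice the
maximum head radius is enforced at placement, so the spine mask has exactly
`n_spines` connected components by construction; infeasible requests fail
with the feasible maximum. Rendering and rater simulation are fully
deterministic given the scene seed.

The simulated annotators detect each spine with a configurable probability
(default 0.85 — consistent with the observed magnitude of human miss rates
in spine annotation), jitter their click by anisotropic Gaussian noise
(default 0.15 um xy, 0.5 um z) and add Poisson false positives placed at
least 1 um from any true structure so they are unambiguous in tests.

Passing tests on this synthetic family demonstrates that the algorithms are
implemented correctly and that the pipeline recovers known ground truth
under realistic geometry, optics and noise. It does *not* demonstrate
segmentation performance on real tissue: the synthetic scenes lack
out-of-focus fluorescence from deep structures, motion and bleaching
artifacts, spine-morphology diversity (stubby/mushroom/thin subtypes),
crossing dendrites, and the label noise of human pixel annotations.
Conclusions about real-data accuracy require the multi-rater benchmark
workflow (`benchmark_reliability()`, `benchmark_segmentation_agreement()`)
on real annotated stacks.

## Numerical choices and degenerate inputs

* Intensity normalization of a constant tile returns all zeros (documented
  rule); normalization is invariant under positive affine maps.
* Voxel centers sit at `(index - 1 + 0.5) * voxel_size`; all distances are
  computed in micrometers, so anisotropy is handled uniformly everywhere
  (rasterization, dilation, flood-fill distance, clustering radii).
* SWC tracings are interpreted in micrometers by default; a `unit = "px"`
  switch converts pixel-unit tracings using the stack voxel size, since
  tracing tools differ in their conventions.
* Capsule rasterization samples interpolated spheres at a quarter of the
  smallest voxel edge — fine enough that the union of spheres is
  indistinguishable from the exact capsule at voxel resolution; a radius-0
  node marks exactly the voxel containing it.
* 16-bit-or-less integer stacks round-trip TIFF exactly; float stacks are
  stored as 32-bit samples, with values outside [0, 1] affine-mapped into
  range and the mapping recorded in a JSON sidecar next to the file.
* ImageJ ROI archives are written per plane (the ImageJ record format is
  2D); each 4-connected in-plane fragment is outlined by its outer boundary
  polygon in pixel-corner coordinates, holes are dropped, and the archive
  is a stored (uncompressed) ZIP written without external tools.
* Ties in flood-fill seed ordering break by array linear order; 2-means
  splits use a fixed seed — all pipeline stages are deterministic given
  their seeds.

## Problem sizes used in validation

The shipped validation and reproduction runs use deliberately compact
problem sizes chosen as the package's own desk-scale conditions: 32 px
fixed tiles for the overfit sanity benchmark (8 tiles, 200 Adam steps);
20 training scenes of 6 x 64 x 64 voxels and ~300 streamed-tile steps for
the end-to-end recovery benchmark, evaluated on 10 held-out scenes; and
5-7 simulated raters over scenes of 4-5 spines for the reliability
recovery checks, aggregated over tens of seeds. Larger models (F = 16/32,
D = 4, 128 px tiles) are fully supported by the same code paths and are
exercised structurally (shape, capacity scaling, determinism) rather than
trained to convergence.

## Known limitations

* Training at the full reference scale (128 px tiles, tens of epochs,
  multi-stack corpora at 2048 x 2048 px) is compute-heavy in pure R; the
  implementation is intended for method development, validation and
  moderate fine-tuning, not GPU-scale training.
* The ImageJ ROI writer emits outer boundaries only; ROIs with internal
  holes lose the holes in the exported outline (the label-volume export is
  lossless).
* `rescale_stack` resamples in xy only; z resampling is out of scope.
* The benchmark reproduction functions expect the open multi-rater
  benchmark data to be downloaded and converted locally; no network access
  is attempted by the package.
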