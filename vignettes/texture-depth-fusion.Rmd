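---
title: "Fusing hand-crafted texture features into a convolutional classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing hand-crafted texture features into a convolutional classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Chest radiographs are grayscale images in which pneumonia presents as
diffuse, texture-like opacities with fuzzy boundaries — exactly the kind of
signal plain convolutional networks tend to summarize away in their deeper,
more abstract feature maps. texfuse implements a hybrid classifier for such
two-class grayscale problems: local texture statistics are extracted with
classical operators (local binary patterns and a histogram of oriented
gradients), rendered back into grayscale *feature images*, and fed through a
second convolutional branch that is merged into a VGG-16-style backbone by
element-wise Add fusion. The fused feature maps carry both the micro-texture
detail of the hand-crafted operators and the abstraction of the learned
hierarchy.

The package covers the whole experimental loop: preprocessing, the texture
operators, the two-branch network with configurable fusion depth, stratified
k-fold training/evaluation with the standard metric suite, parameter sweeps,
and a synthetic radiograph-like image generator so that every stage is
exercisable without any clinical data.

## Preprocessing

`preprocess_image()` crops, min–max normalizes, and resizes. The crop
geometry is configurable because radiograph archives differ: the default
`center_square` keeps the largest centered square (dropping the lateral
background bands typical of chest films) and makes the subsequent
aspect-preserving resize exact; `fixed_margin` trims a fixed fraction per
side; `none` leaves geometry alone, in which case the resize may change the
aspect ratio. Intensities are mapped to $[0,1]$ by $(x - \min)/(\max -
\min)$, with a constant image defined to map to zeros. Resizing is bilinear
on a corner-aligned grid, so resizing to the input size is the identity.
Normalization happens *before* texture extraction; the texture operators are
insensitive to this ordering (LBP codes depend only on intensity ordering,
HOG votes only rescale).

## Local binary patterns

At each pixel the eight neighbors $q_p$ are thresholded against the center
$q_c$ and read as a binary code
$\mathrm{LBP} = \sum_{i=0}^{7} 2^i\, s(q_{p_i} - q_c)$, with $s(d) = 1$ when
$d \ge 0$ — ties deliberately count as 1. Neighbor enumeration starts at the
east neighbor and proceeds counter-clockwise, with bit $i$ weighted $2^i$;
this order is fixed and shared by the production code and the per-pixel
reference oracle in the tests, so all worked examples are self-consistent.

Six variants are provided:

* `default` — the raw 8-bit code (0–255);
* `ror` — rotation-invariant: the minimum over all circular rotations of the
  bit string;
* `uniform` — rotation-invariant uniform: patterns with at most two 0↔1
  transitions are labeled by their popcount, all others share one label
  ($P+2 = 10$ labels);
* `nri_uniform` — non-rotation-invariant uniform: each of the 58 uniform
  patterns keeps its own label (assigned in ascending code order), all
  non-uniform codes share label 58 (59 labels);
* `var` — the population variance (divide by $P$) of the neighbor
  intensities, a contrast measure; the package default, because opacity
  texture is primarily a local-contrast signal;
* `circular` — $P$ bilinearly interpolated samples on a circle of radius
  $R$, raw code, no post-mapping. This is the one variant that accepts
  $P \ne 8$, $R \ne 1$; the grid variants use the exact 3×3 neighborhood.

Borders are replicate-padded by $R$ so the code map keeps the image extent
(a map the network can consume at full resolution); `pad = FALSE` returns
the valid interior only. Rendering divides integer codes by the variant's
maximum possible code, so equal codes always render identically across
images; the unbounded `var` map is min–max normalized per image.

## Histogram of oriented gradients

Gradients are central differences, $F_x = H(x+1,y) - H(x-1,y)$ and $F_y =
H(x,y+1) - H(x,y-1)$, on a replicate-padded image, with magnitude
$G = \sqrt{F_x^2 + F_y^2}$. The orientation is the quadrant-aware angle of
$(F_y, F_x)$, folded to $[0°, 180°)$ by default. A configuration switch
`orientation_formula = "as_printed"` instead uses the angle of $(F_x, F_y)$
— the same field reflected about 45° — for compatibility with sources that
state the arctangent with the axes transposed; both conventions are tested
and yield equivalent descriptors up to that reflection.

The image is partitioned into non-overlapping square cells (default 2 px,
the finest of the supported sweep 2–32; trailing partial cells are dropped)
and each pixel votes its magnitude into the two nearest of 9 orientation
bins by linear interpolation, so each cell's total vote equals the sum of
its pixels' gradient magnitudes — an identity asserted to 1e-9 in the tests.
No block normalization is applied: the descriptor is rendered to an image
rather than fed to a linear classifier, and the per-image min–max
normalization at render time fills that role. Rendering paints each cell
with its maximum bin magnitude (`dominant`, the default — it preserves cell
resolution at cell size 2, where glyphs are unreadable) or draws oriented
line glyphs (`glyph`).

## The fused network

The backbone is the VGG-16 convolutional layout — stages of 2, 2, 3, 3, 3
conv layers (3×3, same padding, ReLU) of widths 64, 128, 256, 512, 512,
each stage closed by a 2×2 max-pool. The classifier head is reduced: the
first of VGG-16's three fully connected layers is removed (it dominates the
parameter count), leaving dropout → FC(4096) → ReLU → dropout → FC(2).
Dropout defaults to 0.5, the value used by the original VGG work.

The LBP and HOG feature images enter as the two channels of a texture
branch with the same stage layout, running up to the fusion position. The
branch has its own weights by default — sharing would force two
heterogeneous inputs through one filter bank — but
`texture_mode = "separate_branches"` with `share_weights = TRUE` is
available for ablation. Fusion is element-wise Add with a learnable
per-channel kernel: $z_i = (x_i + y_i) * k_i$, where $*$ is
cross-correlation, the CNN convention. Kernels are 1×1 and initialized to
identity so training starts from plain addition; Add keeps the feature
dimensionality unchanged, which is what makes it cheaper than channel
concatenation. Fusion can occur at six positions: the input, or after the
last conv of any of the five blocks, *before* that block's max-pool (at
224×224 and full width, the block-3 position fuses at 256×56×56; block 5
fuses at 14×14). At the `input` position the single preprocessed channel is
broadcast across the texture channels and the Add happens in
texture-channel space.

`width_multiplier` scales every layer width by a fraction, preserving the
topology; it exists so that full cross-validation experiments run in
minutes on one CPU, while `width_multiplier = 1` with 224×224 input
reproduces the full-size architecture. Initialization is He-uniform,
seeded. No pretraining is assumed or supported.

The forward and backward passes are written in the package (im2col +
BLAS convolutions in compiled code), and backpropagation is verified
against central finite differences in the test suite — across both
branches, the fusion kernels, and the head.

## Training and evaluation

`make_folds()` produces a stratified, seed-deterministic k-fold assignment
(per-class fold sizes differ by at most one). `train_config()` defaults
are the full-scale regime: Adam at learning rate 1e-4, 50 epochs, batch
64, no early stopping, two-class cross-entropy. The desk-scale experiments
(`experiment_config()` defaults) instead use batch 16 and learning rate
1e-3: with only a few hundred training images, batch 64 would give roughly
two parameter updates per epoch, far too few for the short 10-epoch runs —
the smaller batch and larger step restore a sensible update count. No class
reweighting is applied by default.

`compute_metrics()` reports accuracy, precision, recall and F1 per class
and averaged. The default averaging is support-weighted, which in a binary
task makes averaged recall *algebraically equal* to accuracy (both are
$\sum_c \mathrm{TP}_c / n$); the package computes it through that identity
so the equality is exact, not merely within rounding. A precision or recall
with a zero denominator is defined as 0, with a warning. Macro averaging is
available by flag.

`run_experiment()` chains everything per fold and emits a results bundle
(per-fold and mean metrics, per-sample predictions, the resolved config,
seeds, and a timestamped log); `sweep_axis()` repeats it over the LBP
variant roster, the HOG cell sizes 2–32, or the six fusion positions,
yielding the familiar comparison tables.

## The synthetic generator

`generate_dataset()` emulates two-class grayscale radiograph-like images
whose class difference is carried by local texture. Both classes share a
smooth background — Gaussian-filtered white noise (amplitude 0.15,
correlation length 8 px) plus a vertical brightness gradient — and
low-amplitude horizontal sinusoidal bands (amplitude 0.05, spacing 12 px)
standing in for rib shadows; the bands exercise HOG's orientation response
and the filtered noise exercises LBP's micro-texture response. The
"pneumonia" class additionally receives 3–7 soft-edged blob opacities
(Gaussian profile, radius 3–8 px, center intensity +0.3) carrying fine
noise (sd 0.12) inside the blob, placed uniformly within a central
elliptical lung-field mask so class membership cannot be read off border
artifacts. Images default to 64×64 — chosen once so that a full
cross-validated run takes minutes, not hours — and the generator accepts
224×224 for full-architecture smoke tests. Output is 8-bit PNG and is
bit-identical under a fixed seed.

Setting the blob intensity delta and texture noise to zero yields the null
construction: the two classes are then distributionally identical, which is
used to verify that no stage of the pipeline leaks labels (cross-validated
accuracy must sit at chance) and that the permutation test below keeps its
nominal type-I error.

`texture_separation_check()` quantifies, before any training, whether the
two classes actually differ in the statistics the texture operators see:
each image is summarized by its LBP code histogram plus mean gradient
magnitude, features are standardized over the pooled sample, and the
Euclidean distance between class means is compared against a label
permutation null (999 permutations by default).

What the generator does **not** emulate: anatomy (no lungs, mediastinum or
bone structure), acquisition physics, scanner and positioning variation,
label noise, or the class imbalance of clinical archives. Passing tests on
this generator demonstrate that the pipeline is correctly wired and can
learn a texture-borne class signal; they say nothing about clinical
performance, which requires large clinical archives and GPU-scale
training of the full-width architecture.

## Numerical choices and degenerate inputs

* LBP ties ($q_p = q_c$) set the bit to 1, exactly as the sign convention
  states; monotone-intensity invariance therefore holds in the absence of
  ties.
* Min–max normalization of a constant image returns zeros (both in
  preprocessing and in rendering), avoiding 0/0.
* HOG votes at an exact bin center land wholly in that bin; the two-bin
  linear interpolation conserves every vote by construction.
* Crops smaller than 3×3, images smaller than the LBP neighborhood or the
  HOG cell, non-2-divisible network inputs, mismatched Add shapes, and
  classes smaller than k all raise validation errors naming the offending
  quantity.
* Convolutions use zero padding (the CNN convention); the texture
  operators use replicate padding (a border-value convention that avoids
  spurious edges in the code maps). The two choices serve different
  purposes and are each stated where they apply.

## Study conditions used by the checks

The package's end-to-end checks run at fixed desk-scale conditions, stated
here as the package's own operating point: 100 images per class at 64×64,
width multiplier 1/8, 2-fold cross-validation, 10 epochs, seeds
{101, 202, 303}; the fused model is required to reach mean CV accuracy
≥ 0.85 and not be beaten by the depth-only ablation in the majority of
seeds, and the null construction must stay within [0.35, 0.65]. The
`scripts/acceptance.R` script recomputes the same quantities from scratch
for any seed.

## Known limitations

* The compiled kernels are plain im2col convolutions on one CPU thread; the
  package is built for method verification at desk scale, not for training
  full-width 224×224 models, which remain GPU-scale work.
* JPEG input requires the EBImage package; PNG is handled natively.
* The fusion kernel is per-channel (depthwise); a full cross-channel
  projection at the fusion point is out of scope, as are concatenation
  fusion, pretrained weights, and the comparison baselines
  (MobileNet-class networks and friends).
* `var` LBP rendering is per-image normalized because the variance is
  unbounded; its rendered images are therefore only comparable within one
  image, unlike the integer-coded variants.
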