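---
title: "Methods: patch-based CNN-SVM recognition of IPCL types"
author: "ipclkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based CNN-SVM recognition of IPCL types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the model and its
assumptions, the parameters that matter, the numerical choices, what the
synthetic fixtures do and do not emulate, and the known limitations.

## Scientific setting

Intraepithelial papillary capillary loops (IPCLs) are esophageal
microvessels visible under narrow-band imaging with magnified endoscopy as
brown structures on pink mucosa. Their morphology — sparse near-normal
loops (type A), dilated tortuous loops with intact loop formation (B1),
or dendritically branched / markedly thickened vessels (B2_B3) — tracks the
invasion depth of squamous cell carcinoma. The package treats type
recognition as patch-level texture classification inside clinician-drawn
lesion regions, followed by a spatial synthesis step that paints whole-image
class maps. Types B2 and B3 are merged into a single class because both are
rare and morphologically close, which also mitigates class imbalance.

## Greedy patch tiling (GPGA)

A convolutional classifier needs fixed-size inputs, while annotated lesion
regions are irregular. The tiler scans candidate upper-left corners on a
regular grid in raster order (row-major, top-left first) and accepts a
candidate when

* **Rule 1 (containment)** — at least `containment_min = 0.95` of the
  `64 × 64` patch lies inside the region mask, and
* **Rule 2 (overlap)** — its area overlap with every previously accepted
  patch is at most `overlap_max = 0.75`; the set of positions violating
  this around an accepted patch is the "gray area", and testing the
  candidate against the closed form
  `max(0, w−|dx|)·max(0, w−|dy|)/w²` is mathematically identical to
  painting those positions into a mask.

Both thresholds are inclusive (`>= 0.95`, `<= 0.75`), matching their printed
definitions. The candidate stride defaults to `grid_step = 8` px: a stride-8
grid still permits 87.5% linear overlap, so Rule 2 binds before the grid
does, while keeping the candidate set desk-scale. Greedy raster order makes
the result deterministic; the suite verifies on randomized masks that the
output is *maximal* (no remaining grid candidate satisfies both rules) and
re-checks every output with an independent brute-force verifier.

## Augmentation

Augmentation operates on whole images before tiling, because re-running the
tiler on a transformed image yields genuinely new patch positions rather
than replicated pixels:

* **Rescaling pyramid.** Side lengths follow `d_i / d_j = k^(i−j)` with
  `k = √2`; mode `S5` is the native scale and modes `S3–S7` span a 4×
  magnification range. Pixels are resampled bilinearly, masks with
  nearest-neighbor (then re-binarized) so labels stay crisp. A result
  smaller than the patch side is a degenerate-scale error.
* **Rotation/flip.** Modes `F0–F3` rotate counterclockwise by multiples of
  90°, `F4–F7` flip horizontally first. The eight modes realize the
  dihedral group of the square; the mode list is an enumeration choice
  (the symmetry set itself is not). Exact 90° rotations are lossless.
* **Cropping.** Optional 56/64 crop: uniform random offsets during
  training, the center crop (floor division: offset 4) at test time.
  Cropping is **off** in the flagship configuration — on patch-scale
  texture it removes context without improving accuracy — so the default
  network input stays 64 px.
* The `[F0–F7]/2` configuration (random 50% downsampling) samples per
  patch with a seeded RNG; the sampling unit is an implementation choice
  documented here.

## NBI-Net

The network is deliberately small — annotated endoscopy datasets are
thousands of patches, not millions of images:

| stage | layer | parameters |
|---|---|---|
| 1 | conv1: 64 filters, 7×7, stride 2, pad 0 | ReLU |
| 2 | pool1: max 3×3, stride 2 (overlapping) + LRN | — |
| 3 | conv2: 256 filters, 3×3, stride 1, pad 0 | ReLU |
| 4 | pool2: max 3×3, stride 2 | — |
| 5 | fc1 1024 → fc2 128 → fc3 3 | ReLU + dropout 0.5 on fc1/fc2, softmax |

Shape arithmetic uses **floor** for convolutions and **ceiling** for
pooling; this is the only pair that reproduces all eight reference spatial
sizes (64→29→14→12→6 and 56→25→12→10→5), and any other rounding pair is
falsified by at least one of them (ceiling-conv gives 30 at conv1;
floor-pool gives 5 at pool2). The conv1 stride of 2 with zero padding is
likewise forced by 64→29 under a 7-px kernel — a derivation, not a guess.
Ceiling-mode pooling windows may overhang the input; the overhang is padded
with −∞ so clipped windows simply ignore it. The stride < window ("overlapping")
pooling and the dropout are regularizers appropriate to the small data
regime.

Choices the architecture description leaves open, fixed here and exposed in
the configuration:

* **LRN placement and constants** — after pool1 only, cross-channel form
  `scale = 1 + (α/n) Σ a²` with `n = 5`, `α = 1e−4`, `β = 0.75` (the
  convention of the framework family this design derives from). LRN is
  shape-neutral either way.
* **Optimization** — momentum 0.9, weight decay 5e−4, batch size 64,
  He-style seeded initialization. The learning rate starts at 0.01
  (0.005 as the documented alternative) and decays tenfold twice, at 50%
  and 75% of the epoch budget; the published schedule gives the two decays
  but not their timing.
* **Preprocessing** — per-channel mean removal only, with the mean
  computed on the training split and stored in the fitted model.

Training is deterministic given the seed: initialization, shuffling and
dropout all draw from one seeded stream, and the BLAS kernels are
single-threaded. The convolution and pooling kernels run in single
precision (standard arithmetic for CNN training; the package keeps a pure-R
double-precision reference implementation of every kernel, pinned to the
compiled path by parity tests and to numerical differentiation by a
gradient check).

Feature extraction returns fc activations after the affine transform and
its ReLU where present (fc1: 1024-d, fc2: 128-d) and the pre-softmax logits
for fc3 (3-d), with dropout disabled.

## Hybrid SVM head

The soft-margin SVM (`min ½‖w‖² + C Σ ξᵢ` s.t. `yᵢ(wᵀxᵢ + b) ≥ 1 − ξᵢ`)
replaces the softmax at prediction time. Multiclass uses one-against-one:
three pairwise classifiers for three classes, majority vote. `C` defaults
to 1.0 (unstated in the source design; exposed, with `{0.1, 1, 10}` the
suggested grid), the RBF width defaults to `1/dim`, and features are
standardized by default because CNN activations are nonnegative and
scale-skewed. Vote ties are possible with three classes; they resolve by
the largest summed absolute decision value among the tied classes, then by
the fixed class order A < B1 < B2_B3 — an artifact convention, stated so
results are reproducible. PCA before the SVM is available but off by
default. The binary solver is libsvm (via e1071) at tolerance 1e−3; tests
pin it against a brute-force primal search on small instances.

## Classical descriptors

The three conventional baselines use the stated configurations, which fix
their dimensions exactly (PHOW 4000, LBP 928, PHOG 680):

* **PHOW** — dense SIFT (4×4 spatial bins × 8 orientations = 128-d) at bin
  sizes {4, 6, 8} and stride 4 (the multi-scale set is open in the source;
  these values suit 64-px patches and are exposed), grayscale, quantized
  against a 200-word k-means codebook and histogrammed over the {2×2, 4×4}
  pyramid, per-cell L1 normalization. Flat (zero-gradient) windows yield
  zero descriptors and are discarded; codebooks are fit on training folds
  only to avoid leakage.
* **Uniform-58 LBP** — 8 neighbors at radius 1 (diagonals sampled
  bilinearly), threshold at the center with ties counting as ≥, only the
  58 patterns with ≤ 2 circular transitions kept (the 928 = 16 × 58
  dimension forces discarding rather than pooling non-uniform patterns),
  histograms per 16×16 cell, L1-normalized.
* **PHOG** — signed gradient orientations over [0°, 360°) in 8 bins,
  magnitude-weighted, over the {1×1, 2×2, 4×4, 8×8} pyramid, per-level L1
  normalization.

## Synthesis and evaluation

Patch predictions are painted back into the image frame by
**Gaussian-weighted voting**: each patch adds
`exp(−‖p − center‖² / (2σ²))` over its own footprint to its predicted
class's score plane. The mechanism's width, support and aggregation rule
are open in the source design; the package fixes σ = w/4 (the weight falls
to ~2×10⁻⁴ at the patch corner, so votes are strongly center-weighted),
truncates support to the patch footprint, accumulates additively (hence
order-independently), and casts hard class votes by default with
probability-weighted votes as an option. Patches from augmented frames are
mapped back through the inverse rotation/flip and rescale before voting;
test-time augmentation is off by default. The overlay colors the argmax
class per covered pixel green/blue/red for A/B1/B2_B3, ties broken
A > B1 > B2_B3, uncovered pixels transparent.

**Case-level cross-validation**: images of one patient case share texture
characteristics and patches overlap, so folds are assigned to whole cases
(seeded shuffle, round-robin within class for stratification) and every
patch inherits its case's fold — patch-level slicing would leak test
texture into training. The package defaults to k = 3 at fixture scale
(k = 5 is the general default in `make_folds()`; the fold count is not
prescribed by the source design). Metrics: aggregated accuracy (pooled
over all folds before dividing), a 3×3 confusion matrix, and per-class
average precision (precision at each positive's rank, no interpolation,
one-vs-rest), macro-averaged.

## The synthetic fixture generator

Real NBI-ME data is private, so every stage is exercised on procedural
fixtures that reproduce the *structure* of such a dataset:

* patient cases (default 4 per class) with 3 images each at 400×400 px,
  one irregular star-polygon lesion region per image covering 10–40% of
  the image;
* three visually distinct vessel textures drawn inside the region —
  sparse small dots (A), closed loops of varying diameter (B1), and
  random-walk branching strokes, distinctly thicker (B2_B3) — matching
  the qualitative clinical type definitions;
* a brown-on-pink palette (foreground near RGB 120/60/50, background near
  210/160/150) with per-case color jitter, emulating hemoglobin contrast;
* a per-image linear illumination gradient (amplitude 0.25) and additive
  Gaussian noise (σ = 8 intensity units), emulating non-uniform
  illumination and camera noise;
* per-image texture scale jitter (0.85–1.18), emulating magnification
  variation and giving the rescaling augmentation something to normalize.

Texture element densities and stroke geometry were chosen once for visual
distinctness at desk scale and are exposed in `fixture_config()`. The
generator is byte-deterministic under its seed (pixels are quantized to
8 bits in memory so the arrays equal their PNG round-trips), regions are
generated as polygons and rasterized with the half-open even-odd rule so
polygon and mask annotations agree exactly, and per-case parameter sharing
makes patches from one case correlated — precisely the property that makes
case-level cross-validation necessary.

What the fixtures do **not** emulate: real mucosal background texture,
specular highlights, vignetting, motion blur, continuous severity grades
between types, inter-annotator variability in label curves, and the heavy
class imbalance of clinical collections. Passing the suite therefore
demonstrates that the pipeline's machinery is correct and that it can learn
genuinely case-generalizing texture distinctions — not that clinical-grade
accuracy would transfer to endoscopy data.

## Problem sizes and numerical choices

The test suite trains at fixture scale: the cross-validated end-to-end
check uses 3 classes × 4 cases × 3 images (≈ 2,000 patches), 10 epochs per
fold, 3 folds — a configuration a laptop core completes in minutes per
fold. Degenerate inputs are defined behavior throughout: a region too small
to satisfy Rule 1 yields zero patches; a constant patch yields zero PHOW
descriptors, a single-bin LBP histogram and a zero PHOG level after
normalization guards (`0/0 → 0`); an empty vote map colorizes to full
transparency. Exact ties (LBP threshold, vote argmax, overlap boundary)
are resolved by documented inclusive rules rather than floating-point
accident; the LBP comparison carries a 1e−9 tolerance so bilinear rounding
cannot flip an exact tie.

## Known limitations

* The published patch corpus (~6.5k patches from 261 clinical images)
  cannot be reproduced: the candidate stride and scan order of the
  original tiler are unstated, and the data is private. Patch counts here
  are therefore properties of the fixtures, not targets.
* The footprint of a patch mapped back from a rescaled frame is
  approximated by a patch-sized axis-aligned square around the mapped
  center (exact for rotations/flips, nominal for scale).
* Training runs single-threaded for determinism; the engine is an
  im2col + BLAS design and does not use a GPU.
* The SVM head is one-against-one with hard votes; probability calibration
  and one-vs-rest are out of scope, as are descriptor fusion and model
  ensembles.
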