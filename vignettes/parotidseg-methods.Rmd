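---
title: "Valid-convolution U-Nets for parotid gland segmentation: models, training strategies and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valid-convolution U-Nets for parotid gland segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The parotid glands are radiosensitive salivary glands that must be spared
during head-and-neck radiotherapy. Delineating them on the planning CT is
slow to do by hand and hard to automate: the gland's soft-tissue contrast to
its surroundings is low (a few tens of HU), its shape varies, and dental
metal artifacts often run right through it. `parotidseg` implements a family
of convolutional segmenters for this task together with the training
machinery that makes them work on a structure occupying well under 1% of the
scan volume, and an evaluation suite to compare them.

Three model variants are provided, all derived from the same
three-resolution-level, valid-convolution (unpadded) U-Net template:

* a **2-D U-Net** applied to axial slices, trained with a region-of-interest
  (ROI) sampling strategy;
* a **2-D ensemble**: three 2-D U-Nets on axial, coronal and sagittal
  reformats, fused by a per-voxel 2-of-3 majority vote;
* a **3-D U-Net** trained on patches with controlled batch composition.

All networks solve a binary task (left parotid only, two softmax output
channels); right-sided references are converted into left-sided training
cases by sagittal mirroring.

## Architecture arithmetic

Each block applies two unpadded 3-voxel convolutions (batch normalisation +
ReLU after each); 2-fold max-pooling separates the three encoder levels, and
the decoder uses 2-fold nearest-neighbour upsampling followed by a
centre-cropped skip concatenation, ending in a 1-voxel convolution and a
channel softmax. Because no convolution pads, every layer shrinks the
feature maps: the network classifies only a centre region of its input, and
the surrounding margin is context. With the defaults the per-axis reduction
is 40 voxels and the maximum receptive field is 44 voxels per axis, i.e.
44 x 44 x 88 mm at the 1 x 1 x 2 mm working resolution; a 72 x 72 x 56
input patch classifies its central 32 x 32 x 16 voxels.

These numbers are not assumed anywhere: `valid_output_size()` and
`receptive_field()` derive them symbolically from the layer list, and
`measure_receptive_field()` re-measures the receptive field empirically by
perturbing single input voxels of a constructed network (with
positive-valued probe weights, so cancellation cannot hide a connection).
The receptive-field trace uses interval arithmetic through the reversed
layer list; the nearest-neighbour upsampling floors indices, so the interval
length depends on output-voxel parity and the reported value is the maximum
over parities, which is the figure conventionally quoted for U-Nets.

Choices the architecture description leaves open, fixed here as
configuration defaults: nearest-neighbour upsampling + convolution rather
than transposed convolution (either satisfies the size arithmetic); batch
normalisation after each convolution before the ReLU; base width 32 doubling
per level (tests and desk-scale experiments use widths 1-8 to stay within
CPU budgets — connectivity, and hence all geometry checks, do not depend on
width); He-initialised weights as a pure function of a seed.

## Class balancing: why and how

A parotid is a ~30 ml structure in a ~10 l scan. Uniform sampling would
show the network almost pure background, so two strategies raise the
foreground frequency:

**ROI slice training (2-D).** Training slices are drawn only from the slice
range containing the gland, extended by 5 slices per side in view direction
(so the network also sees gland-free neighbouring slices and learns to stay
quiet there); sagittal/coronal reformats additionally restrict the z range
to 25 voxels above/below the gland, since the head-and-neck scan range along
z is large. The margin is read as per-side; the interval arithmetic is
`[first - 5, last + 5]` clipped to the volume.

**Controlled batch composition (3-D).** Patches are drawn from the whole
volume, but every minibatch is composed so that exactly
`round(batch_size * fg_fraction)` patches (default 50%) contain at least
one foreground voxel inside their classified centre. "Overlap" is
interpreted on the centre region, not the input context, because only the
centre reaches the loss. Foreground placement samples a foreground voxel
and jitters the centre region around it, which is uniform over admissible
positions without enumerating them; background patches are uniform with no
exclusion (they may, and occasionally do, contain gland voxels). Out-of-
volume context is mirror-padded.

## The loss, and a pitfall the balanced batches expose

All training minimises a smoothed soft Dice loss
`1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1e-5`
(`soft_dice_loss()`), which is insensitive to the foreground/background
imbalance. One implementation detail matters greatly: the loss is pooled
over the minibatch (one overlap/mass sum across all patches), not averaged
per patch. For a pure-background patch the per-patch loss is
`1 - eps/(sum(p) + eps)`, whose gradient is of order `eps / sum(p)^2` —
numerically zero. Averaging per patch therefore silences exactly the
background patches that the balanced composition adds, and the model never
learns to suppress distant false positives (we observed precisely this
failure before pooling). With batch pooling, background predictions enter
the shared denominator and receive a genuine downward gradient.

Optimisation uses Adam (default learning rate 1e-3; the harnesses use 3e-3
for the small desk-scale networks), with batch-normalisation statistics
accumulated as running means (momentum 0.1) for inference.

## Inference, fusion, postprocessing

Because valid convolutions are shift invariant, a volume can be tiled by
non-overlapping classified-centre blocks, each computed from its
mirror-padded context, and the stitched result is bit-identical to a single
whole-volume pass (`predict_3d_tiled()` vs `predict_3d_whole()`; the test
suite asserts equality, and an analogous check holds for in-plane tiling of
2-D slices). The 2-D ensemble binarises each view's prediction and takes a
per-voxel 2-of-3 majority vote — voting on binarised masks, not averaged
probabilities, matching the ensemble definition used with these models.

Postprocessing thresholds at 0.5 (inclusive: `p >= 0.5` is foreground),
keeps the largest 6-connected component, and resamples to the original grid
by nearest neighbour. The Dice-trained networks emit near-binary maps, so
nothing fancier is needed. Edge conventions: equal-size component ties go to
the component containing the lowest linear voxel index (determinism over an
event of measure zero); an empty binarisation is a valid result (flagged,
not an error), since a segmenter may legitimately find nothing.

## Preprocessing

Clinical volumes arrive at ~1 mm in-plane and 2 or 3 mm slice spacing, so
resampling runs along the transverse axis only (1-D Lanczos, support 3),
preserving in-plane detail. Grid rule: the first output slice sits at the
first input slice and the output has `floor(extent/target) + 1` slices —
origin-anchored and reproducible. Kernel weights are renormalised per output
sample (constants survive exactly); out-of-range samples clamp to the edge
slices; Lanczos ringing is deliberately not clamped. The treatment couch is
removed by a deliberately simple segmentation — threshold at -300 HU,
largest 6-connected component, per-slice hole fill — which is one of many
valid choices for a couch that does not touch the patient; voxels outside
the body mask are set to -1024 HU. Network inputs are normalised by a fixed
soft-tissue window (clamp to [-160, 240] HU, affine to [-1, 1]); per-volume
statistics are avoided since CT is calibrated.

## The phantom: what a green test does and does not establish

`generate_phantom()` builds a desk-scale stand-in for a head CT: an
elliptical body (soft tissue, 40 HU) in air, one lateral ellipsoidal gland
per side at +20 HU contrast, optional midline distractor blobs at 55-65 HU
(gland-like intensity, un-gland-like position), an optional couch slab,
optional streak pairs through the gland, Gaussian noise (sigma 10 HU, a
typical planning-CT soft-tissue noise level), at 1 x 1 x 2 mm spacing. The
default grid is 96 x 96 x 48 voxels — a miniature head, chosen once so that
CPU training on a cohort finishes in minutes. Masks are exact rasterised
ellipsoids; everything is a pure function of the seed. The right gland is
generated independently rather than mirrored, so the mirroring augmentation
is genuinely exercised.

The phantom reproduces the *mechanisms* the pipeline must handle — low
contrast, lateralised targets, confusable structures far from the ROI,
couch, anisotropy — not clinical anatomy. A model reaching Dice >= 0.85 on
held-out phantoms (the end-to-end test bar) demonstrates that the training
and inference machinery works end to end; it says nothing about clinical
performance, where reported parotid Dice values for such models are around
0.83-0.88 on curated data and depend on hundreds of real scans.

One qualitative clinical finding does replicate at phantom scale and is
asserted directionally in the tests: an ROI-trained 2-D model, which never
saw slices outside the gland region during training, produces large false
positives in distant body regions (full-volume Dice well below ROI-restricted
Dice), while the 3-D model trained with balanced whole-volume patches shows
no such gap.

## Evaluation

`dice()` implements the voxel-set overlap `2|X∩Y| / (|X|+|Y|)`. The signed
average surface distance `assd()` averages signed Euclidean distances
between border voxels: border = foreground voxels with a 6-neighbourhood
background (or out-of-volume) neighbour; distances are between voxel centres
in mm; sign is positive outside the reference and negative inside, so
overestimation gives positive ASSD and underestimation negative. The
argument order fixes X = prediction, Y = reference, which makes the sign
convention coherent. The fast path computes O(|∂X|·|∂Y|) minimum distances
in C++ and is validated in the tests against an independent brute-force
implementation of the definition on random small masks.

`wilcoxon_compare()` performs the paired two-sided signed-rank test at
level 0.05: zero differences dropped, exact distribution for n <= 25
without ties, otherwise normal approximation with tie/continuity
correction; all-zero differences return p = 1 by convention.
`run_size_experiment()` trains one model per nested training subset
(`select_training_subsets()` shuffles once and takes prefixes, so curves
are comparable) and reports per-size Dice distributions with unadjusted
adjacent-size comparisons.

One trend does **not** replicate at desk scale: the clinical observation
that more training cases improve the Dice score (up to a plateau). That
comparison presupposes training every subset size to convergence. Under the
fixed small step budget a CPU test run can afford, a model trained on 5
phantoms sees each case thirty times and can beat a 20-phantom model — the
experiment then measures the step budget, not the data quantity. The
experiment runner (`run_size_experiment()`) is implemented and tested
structurally, but the monotone trend is not asserted by the suite.

## Known limitations

* NIfTI/MetaImage support is minimal by design: scalar 3-D images,
  spacing/origin honoured, orientation matrices not applied (arrays are
  taken in stored order); DICOM and RT-STRUCT are out of scope.
* The couch-removal algorithm assumes a couch that does not touch the
  patient; head rests or immobilisation masks in contact with the skin
  would merge with the body component.
* CPU training limits realistic widths/epochs; the defaults here are sized
  for phantoms, and clinical-scale training would need the full-width
  configuration on a GPU.
* Only binary (single-structure) segmentation is implemented; the
  architecture's two output channels are fixed.
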