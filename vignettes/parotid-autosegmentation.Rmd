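---
title: "Attention-gated U-Net segmentation of parotid glands and tumors: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated U-Net segmentation of parotid glands and tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parotidseg)
```

## The problem

Parotid tumors are rare head-and-neck neoplasms that arise inside the
parotid salivary glands, one on each side of the face. On MRI they are
delineated jointly with the gland: because a tumor lies inside its gland,
the four regions of interest (left parotid, right parotid, left tumor,
right tumor) are *nested, non-exclusive* targets. `parotidseg` implements a
complete 2D deep-segmentation pipeline for this task on co-registered
multi-sequence MR images — T1-weighted (`T1w`), T2-weighted (`T2w`) and
contrast-enhanced T1-weighted (`T1wC`) — together with the synthetic
phantom machinery needed to exercise and test every stage without patient
data.

## The network

The model is a 2D U-Net that maps a `(512, 512, C)` multi-sequence slice to
`(512, 512, 4)` per-ROI probability maps.

* **Encoder.** Conv blocks (3×3 convolution → batch normalization → ReLU)
  at five resolution levels with 2×2 max pooling between them. The default
  allocation `c(2, 2, 2, 3, 3)` places 12 conv blocks alongside the 4
  pooling stages; any allocation with at least one block per level is
  accepted through `model_config()` because the reference architecture
  drawing is not dimensionally annotated — the 12/4 count is the firm
  constraint.
* **Decoder.** Bilinear ×2 upsampling followed by a conv block, then a
  merge conv block after each skip connection. Filter counts double per
  level from `base_filters` (64 by default), the standard U-Net convention.
* **Attention gates.** Each skip connection is gated: the skip map and a
  gating signal are projected by 1×1 convolutions to an intermediate
  channel count (half the skip channels), summed, passed through ReLU,
  projected to one channel and squashed by a sigmoid. The resulting mask in
  `[0, 1]` multiplies the skip features, so irrelevant regions are zeroed
  while the region of interest passes unchanged. The gating signal is the
  **bottleneck** feature map — the network's deepest, most contextual
  representation — rather than the adjacent decoder level used by the
  standard attention U-Net; both wirings are built in
  (`gate_source = "bottleneck"` / `"adjacent_decoder"`), and the standard
  wiring doubles as the registered comparison slot.
* **Output.** A 1×1 convolution and an *element-wise sigmoid* per channel.
  There is no softmax: ROIs are not mutually exclusive (a tumor pixel is
  also a parotid pixel), so per-pixel channel sums may exceed 1.

One implementation note: the gate projection is applied at the gating
signal's native resolution and the projected map is then resampled
bilinearly to the skip resolution. Because a 1×1 convolution acts
per pixel and bilinear weights sum to one, this is exactly equal to
resampling first and projecting afterwards, while avoiding a
`512 × 512 × 1024` intermediate tensor.

All layers — convolution (im2col + BLAS), batch normalization, pooling,
bilinear resampling, the gates and the full reverse-mode pass — are
implemented in this package (R with C++ kernels). The backward pass is
verified against central finite differences in the test suite, for both
gate wirings.

## Training

* **Loss.** `1 − DICE` in soft form: per channel and batch item,
  `soft_dice = (2·Σ p·t + s) / (Σ p + Σ t + s)`, averaged, with
  `loss = 1 − mean(soft_dice)`. The smoothing constant `s = 1` (exposed as
  `loss_smoothing`) is needed because the raw ratio is undefined on
  background-only channels, which are common: every axial slice of every
  patient enters training, including slices with no foreground, since
  those teach the null output. At `s = 0` and binary predictions the loss
  is exactly `1 − dice()` from the metrics module; the suite asserts this
  cross-module identity.
* **Optimizer.** RMSprop with learning rate `1e-4` and 200 epochs as the
  study defaults; both are plain `train_config()` values. No schedule and
  no early stopping by default; best-validation-checkpoint selection
  exists behind `keep_best` but is off, matching the fixed-epoch protocol.
* **Normalization.** Each sequence volume is min–max scaled to `[0, 1]`
  per patient. We read "centralized to 0.5 and scaled to [0, 1]" as a
  single min–max map whose midpoint lands at 0.5, with constant volumes
  pinned at 0.5; the alternative reading (a mean-shift to 0.5) would
  require a second rescaling step that is nowhere described.
  Normalization is per volume, not per slice, so intensities remain
  comparable across the slices of one patient.
* **Augmentation** (on the fly, order affine → mirror → gray):
  * *Gray disturbance*: one multiplicative factor from `[0.9, 1.1]` and
    one additive shift from `[−0.1, 0.1]` per sample — scalars, not
    per-pixel fields — then clipping to `[0, 1]` to keep inputs on the
    normalized scale (the clip is our addition; without it inputs leave
    the range the model is normalized for).
  * *Affine disturbance*: one in-plane rotation/scale/translation applied
    identically to image (bilinear) and label (nearest-neighbor,
    re-binarized). The magnitudes (±10°, scale `[0.95, 1.05]`, translation
    ±5% of width) are config-exposed defaults: the source protocol defers
    its exact ranges to earlier work without printing them.
  * *Mirroring with label swap*, probability 0.5: a left/right flip is
    only anatomically valid if the lateral label channels are exchanged
    (left↔right parotid, left↔right tumor). The operation is an involution
    and conserves per-channel foreground counts up to that permutation.
* **Cross-validation.** Patient-level 10-fold splits: a random permutation
  under the seed, validation sets differing in size by at most one, every
  patient validating exactly once (285 patients yield 28- or 29-patient
  validation folds). All slices of one patient stay on one side. Per-fold
  seeds are `seed + fold_index`, so folds are independent but the whole
  run is reproducible bit-for-bit.

## Evaluation metrics

Four metrics per ROI per patient, computed in 3D on the native
anisotropic grid (head-and-neck protocols acquire slices 4–7.2 mm thick
over 0.4–1 mm pixels, and volumes are deliberately *not* resampled to
isotropy):

* `DICE = 2|A∩B| / (|A| + |B|)` and `JACCARD = |A∩B| / |A∪B|`, exact
  voxel-count ratios satisfying `J = D / (2 − D)`.
* `HD95`: surface-to-surface Euclidean distances in mm (voxel centers
  scaled by the spacing) are computed in both directions, pooled, and the
  95th percentile (linear interpolation) is returned. Pooling both
  directed sets is one of two conventions in the literature; the
  max-of-directed-percentiles alternative is selectable
  (`pooling = "max_directed"`).
* `AHD`: the mean of the two directed average surface distances.

Degenerate cases are deterministic and flagged: both masks empty gives
overlap 1, exactly one empty gives 0, and surface distances are undefined
(`NA`, excluded from aggregation with counts reported) unless both masks
are nonempty. Surfaces are voxel-center point sets (foreground voxels with
a background face-neighbor); mesh-based distances are out of scope.
Cohort aggregation reports per-ROI means and a 95% range, read as the
empirical 2.5th–97.5th percentile across patients; a normal-theory CI of
the mean is available as `interval = "mean_ci"` since the reporting
convention admits both readings.

## The phantom generator

The study's patient images are private, so the package ships a generator
whose output drives every test: 3-channel volumes on an anisotropic grid
(default 32×512×512 at 5×0.5×0.5 mm; a small 8×64×64 preset for fast
tests) containing two parotid-like ellipsoids placed symmetrically about
the midline, with tumor ellipsoids strictly inside the gland(s) chosen by
`laterality`. Ellipsoids were chosen deliberately: smooth closed shapes
give well-defined surfaces for HD95/AHD testing, and voxel-center
rasterization makes tumor ⊆ parotid provable (the tumor's normalized
offset magnitude plus its radius fraction is kept below 1 in the gland's
own metric). Per-sequence contrast differs (parotid T1-bright, tumor
T2-bright and strongly enhancing on `T1wC`), so sequence-subset ablations
have signal to find; the specific intensity values are artifact choices —
no per-tissue intensity statistics were available to copy. Cohort
laterality is sampled at 44.6/49.1/6.3% left/right/bilateral, the
observed clinical mix. Anatomical-left is placed on the image-right half
(radiological display), recorded in the manifest.

What phantoms do *not* emulate: bias fields, k-space artifacts,
registration error between sequences, intensity heterogeneity inside
tissues beyond additive Gaussian noise, or realistic organ shape
variation. Passing tests therefore demonstrate the pipeline's
correctness — data flow, geometry, losses, metrics, bookkeeping — not
clinical segmentation accuracy.

## Numerical choices and degenerate inputs

* Batch norm uses batch statistics in training and running statistics
  (momentum 0.1, `eps = 1e-5`) at inference; a duplicated input in a batch
  yields a duplicated output at inference.
* Bilinear resampling uses half-pixel centers with clamped edges; its
  adjoint is the exact transpose (asserted by inner-product tests).
* Convolution weights are He-normal initialized under the model seed; two
  builds with one seed are bit-identical.
* `quantile(type = 7)` (linear interpolation) everywhere a percentile is
  taken.
* Grid fitting center-crops or symmetrically zero-pads to the square model
  input and records the mapping, so predictions are placed back on the
  native grid; foreground is conserved whenever it lies inside the
  retained window.
* Constant-intensity volumes normalize to 0.5 everywhere; non-finite
  intensities are an error, not a silent fill.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely on phantoms at
reduced scale, chosen so the whole pipeline — including training — runs on
one CPU in minutes: metric oracles on grids up to 16³ with surfaces of at
most a few hundred voxels; the architecture contract at the full 512×512
input; training checks on the 64×64 preset with a depth-3, 8-filter model
(the smoke test overfits four bilateral phantoms to mean hard DICE ≥ 0.8
across the four channels in 30 epochs at learning rate 5e-3, batch size 1,
augmentation off); cross-validation and the seven-combination sequence
ablation on 4–6 phantom cases with 2 folds. The full-scale defaults
(512×512, 64 base filters, 200 epochs, 10 folds) are the shipped
configuration values.

## Known limitations

* 2D slice-wise segmentation: no 3D context across slices (by design — the
  anisotropic spacing argues against isotropic 3D convolution), no deep
  supervision, no test-time augmentation.
* The exact encoder block allocation, filter counts and gate
  parameterization of the reference network are under-specified in prose;
  ours are conventional choices exposed in `model_config()`.
* Whether mirroring is applied in addition to or instead of the affine
  disturbance per sample is unstated; we compose them (affine, then
  mirror, then gray).
* Training at the full 512×512/64-filter scale is computationally serious
  in this pure R + C++ implementation; it is intended for correctness and
  moderate-scale use, not GPU-class throughput.
* Comparison architectures (DeepLab V3, PSPNet) are registry slots only;
  their reference results stem from private data and are not reproduction
  targets.
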