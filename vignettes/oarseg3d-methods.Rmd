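---
title: "Methods: 3D residual U-Net segmentation of head-and-neck organs-at-risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D residual U-Net segmentation of head-and-neck organs-at-risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oarseg3d)
```

## The problem

Radiotherapy planning for head-and-neck cancer requires delineating
organs-at-risk (OARs) — here the brainstem, mandible, left and right parotid
glands, and the cervical spinal cord — on planning CT. Manual delineation is
slow and subject to inter-observer variability; convolutional networks can
automate it, but clinical training sets are small (tens of scans). This
package implements a 3D segmentation pipeline tuned for that small-data
regime: contrast-specific intensity normalisation, a compact residual 3D
U-Net with deep supervision, strongly class-weighted loss functions, heavy
spatial augmentation, and boundary-distance evaluation metrics. A synthetic
CT phantom generator makes every component testable without any clinical
data.

## Window normalisation

CT voxel intensities are calibrated Hounsfield units (HU; air −1024, water
0), so fixed intensity windows are physically meaningful. A window with
level $L$ and width $W$ maps intensity $I$ through the clinician-style ramp

$$x = \operatorname{clamp}\!\left(\frac{I - (L - W/2)}{W},\, 0,\, 1\right),$$

with the level mapping to 0.5 and the edges to 0 and 1. The baseline input
is a single channel with $L=488$, $W=3024$, whose ramp spans
$[-1024, 2000]$ HU and clamps everything denser to 1. The multi-window input stacks three standard diagnostic
windows as channels — soft tissue ($L=40$, $W=400$), bone ($L=400$,
$W=1800$) and brain ($L=40$, $W=80$) — analogous to RGB channels, so the
network sees the same anatomy under three contrast settings at once. The
three (L, W) pairs are standard radiological display values; they are
exposed in the configuration (`windows:` section) because the package
treats them as conventions, not tuned constants.

## Network architecture

The segmentation network is a four-level 3D residual U-Net:

* **Encoder.** Each level is a residual block of two zero-padded
  $3^3$ convolutions with a $1\times1\times1$ projection on the shortcut
  (the block changes channel count, so the projection is always needed),
  with $2^3$ max pooling between levels. Channel progression:
  in→16→32, 32→32→64, 64→64→128, 128→128→256.
* **Decoder.** Three up-sampling stages restore resolution. In *transpose*
  mode each stage is a channel-preserving $2^3$ stride-2 transpose
  convolution; in *resize* mode it is tri-linear up-sampling followed by a
  zero-padded $3^3$ convolution (the classical remedy for transpose-conv
  checkerboard artefacts). After concatenation with the encoder skip, a
  residual block reduces channels: 384→128→128, 192→66→64, 96→32→32.
* **Heads.** The main classifier is a $3^3$ convolution to the six classes
  (background + 5 OARs) followed by a per-voxel softmax. Deep supervision
  adds $1\times1\times1$ bottleneck classifiers at the two upper decoder
  stages whose outputs are tri-linearly resampled to full resolution during
  training; a single learnable balance scalar (through a sigmoid) weights
  the auxiliary losses against the main loss.
* **Normalisation.** Block convolutions are bias-free and followed by
  affine instance normalisation — the training protocol fixes the batch
  size at one, which makes batch statistics degenerate. Projections,
  up-sampling convolutions and heads are bare linear maps.

### How the channel scheme was fixed

The reference description of this architecture pins its four exact
trainable-parameter totals (1-/3-channel input × transpose/resize decoder:
4,896,693 / 4,897,621 / 6,530,997 / 6,531,925) but not the per-level
feature counts. Two deltas follow immediately and tightly constrain the
design: the 928-parameter cost of two extra input channels equals
$2\,(27\cdot16 + 32)$, fixing the stem convolution (in→16) and the first
residual projection (in→32); and the 1,634,304-parameter cost of resize
over transpose decoding equals $19\,(256^2+128^2+64^2)$, fixing three
channel-preserving up-sampling stages at 256, 128 and 64 channels. The
remaining interior widths are *not* uniquely determined by the totals; we
fixed them by constrained search so that all four totals and both deltas
are reproduced exactly and the scheme stays as close as possible to the
classical doubling U-Net layout. Two details of the frozen scheme are
constraint-fitting artifacts rather than aesthetic choices and are called
out as such: the middle width 66 of the second decoder block, and the
single learnable deep-supervision balance scalar. `count_trainable_parameters()`
recomputes the totals from a built network, and the acceptance script
re-derives all four from scratch.

Reduced-width replicas for desk-scale experiments use `width_scale`
(e.g. 1/8), which scales every feature count (the decoder middle widths
revert to the regular 128/64/32 pattern at reduced scale).

## Loss functions

All losses act on softmax probabilities $p_l(x)$ with one-hot targets
$y_l(x)$, with background included as class 0 throughout. Class weights are
normalised inverse frequencies

$$w_l = \frac{f_l^{-\alpha}}{\sum_k f_k^{-\alpha}},$$

with $f_l$ the voxel frequency of label $l$ over the training label maps.
The printed form of this weight formula is notationally ambiguous; we read
it as the normalised inverse relative frequency above, which matches its
stated purpose (class-imbalance correction) and makes the weights sum to
one. $\alpha = 1/3$ is used with the weighted soft-Dice loss and
$\alpha = 0.5$ inside the exponential-logarithmic loss.

* **Weighted soft Dice (wSD):**
  $L = \sum_l w_l \left(1 - \frac{2\sum_V y p + 1}{\sum_V y + \sum_V p + 1}\right)$,
  with the +1 smoothing exactly as written, so a class empty in both
  prediction and target contributes zero.
* **wSD + XE:** the 1:1 linear combination (coefficients configurable) with
  the weighted cross-entropy
  $\frac{1}{|V|}\sum_x w_{l(x)}(-\ln p_{l(x)}(x))$.
* **Exponential logarithmic loss:**
  $L = \mathbb{E}_l\!\left[(-\ln \mathrm{Dice}_l)^{0.3}\right] +
       \mathbb{E}_x\!\left[w_{l(x)}(-\ln p_{l(x)}(x))^{0.3}\right]$,
  where $\mathrm{Dice}_l$ reuses the +1-smoothed soft Dice (one Dice
  definition repo-wide; the smoothing also guards $\ln 0$ for empty
  classes). The first expectation is an unweighted mean over classes, the
  second a mean over voxels. The exponent 0.3 follows the loss's original
  recommended setting.

Probabilities (and Dice values) are clamped to $[\varepsilon, 1]$ with
$\varepsilon = 10^{-7}$ before logarithms — a standard numerical guard.
Every loss has an analytic logit gradient, which the tests verify against
central finite differences.

Deep-supervision aggregation is a weighted sum of main and auxiliary
losses with weights normalised to one. The module-level function
`deep_supervision_aggregate()` uses configured weights; the training loop
uses weights $(1, s, s)/(1+2s)$ with $s = \sigma(\lambda)$ and $\lambda$
the network's learnable balance scalar.

## Augmentation

Each training pair is transformed with a random sequence of: lateral
mirroring ($p=0.5$), which also swaps the left/right parotid label codes so
laterality semantics survive; per-axis shifts of at most 4 voxels ($p=1$;
at 1×1×2.5 mm spacing that is ±4 mm in-plane and ±10 mm axially — the
printed axial figure of ±10 mm corresponds to ±4 voxels on this grid, and
the alternative ±10 mm-as-distance reading remains reachable through
configuration); rotations within ±10° about the left–right axis (cervical
flexion/extension) and the cranio-caudal axis (axial rotation), $p=0.75$;
and isotropic volumetric scaling in [0.90, 1.10], $p=0.5$. There is no
rotation about the antero-posterior axis, which has no cervical-posture
interpretation. All sampled transforms compose into a single affine
resampling (tri-linear for intensities, nearest-neighbour for labels) to
avoid repeated interpolation blur; out-of-field voxels fill with air
(−1024 HU) and background. A pure mirror is an exact index flip, so
mirror∘mirror is bit-identical — a property the tests rely on.

## Training protocol

Adam with initial learning rate $10^{-2}$; the rate divides by 10 whenever
the validation loss fails to improve for 100 epochs (the plateau counter
resets on decay and on every new best), training runs at most 1000 epochs
with early stopping after 250 epochs without improvement. "Improvement"
means a best-loss decrease of at least $10^{-6}$, preventing float-noise
resets. The physical batch size is one volume; gradient accumulation delays
the parameter update so that each update uses the mean of four
single-sample gradients computed at the same parameter state (a simulated
batch of four — the delayed-update form makes this property directly
testable). Validation uses the configured loss on the main output only:
the auxiliaries are a training aid. The best-validation parameter state is
checkpointed and restored at the end.

Cross-validation uses seeded folds with held-out test sets. For 34 cases
in 5 folds the test sizes are 7,7,7,7,6, so every case is tested exactly
once; the printed 5×7 reading (35 > 34) would force one case to repeat,
and that variant is available via `overlap_last = TRUE`.

## Evaluation metrics

Volumetric overlap (DSC) is biased toward structure volume and can hide
clinically relevant boundary deviations, so the primary metrics are
boundary distances. Boundary voxels are foreground voxels with at least
one 6-connected background (or out-of-volume) neighbour. The exact
anisotropic Euclidean distance transform of each mask (computed with the
separable lower-envelope algorithm, voxel-centre to voxel-centre, in mm) is
sampled at the other mask's boundary voxels; the two directed samples are
pooled. The pooled sample's mean is the mean distance-to-agreement (mDTA)
and its 95th percentile is HD95, computed with the exclusive
linear-interpolation convention (`quantile` type 6, plotting position
$(n+1)p$), pinned so results are bit-reproducible: on small boundary
samples this convention reads the worst 5 % of distances rather than
interpolating almost entirely inside the best 95 %. Pooling before
the percentile (rather than a max of per-direction percentiles) is our
reading of "symmetric" evaluation. Empty masks yield `NA` metrics with a
warning and an exclusion flag, never silent zeros. Observer comparisons
use the two-sided Wilcoxon signed-rank test on paired per-case samples;
all-zero differences return the degenerate documented result $p = 1$.

## Synthetic phantoms

`generate_phantom()` builds an HU-calibrated head-and-neck-like volume at
1×1×2.5 mm spacing (default test shape 64×64×16, up to the full crop size
200×200×56): a soft-tissue body ellipsoid (~20 HU) in air, an axial
brainstem tube and a thinner, more posterior cervical-cord tube, a
bone-density (~900 HU) partial-torus mandible arch, and laterally
mirror-symmetric parotid ellipsoids, plus Gaussian noise (SD 12 HU) and a
mild 1-2-1 smoothing for partial-volume blur. Organ placement is exactly
symmetric about the mid-sagittal plane, which makes the mirror-swap
invariance of the label maps exactly testable. A simulated second observer
is derived by warping each organ with an independent smooth random
in-plane displacement field scaled so that organ's maximum displacement
equals 2 mm (and clamped so no voxel moves farther) — emulating
slice-wise inter-observer contouring variability with a known per-organ
bound, so every organ's boundary measurably moves.

What the phantoms do *not* emulate: real anatomical variability, imaging
artefacts (beam hardening, metal), low-contrast organ boundaries, or
truncated organs. Passing the phantom convergence test therefore shows the
pipeline is implemented and trainable end-to-end, not that it reaches
clinical accuracy; clinical benchmark tables require the external datasets
and GPU-scale training and are deliberately out of scope.

## Problem sizes and numerical choices

The test suite and examples run entirely on one CPU. Sizes were chosen
once as the package's own desk-scale study conditions: the convergence
test trains a width-scale-1/8 three-channel network with the
exponential-logarithmic loss on eight 32×32×16 phantoms (one held out for
validation, one fresh phantom for testing) for up to 60 epochs with
gradient accumulation of 4 — it reaches DSC above 0.8 for all five organs
in a few minutes. The metric oracle check uses 100 random mask pairs in
8×8×4 volumes at spacing (1, 1, 2.5) against a brute-force all-pairs
oracle at $10^{-9}$ mm. Volumes whose dimensions are not divisible by
$2^3$ are symmetrically zero-padded for the forward pass and cropped back.
Argmax ties break toward the lowest class index (background first).
Instance-norm uses $\varepsilon = 10^{-5}$; He initialisation throughout;
all randomness flows from a single integer seed per entry point.

## Known limitations

* The interior channel widths of the reference architecture are a
  constrained reconstruction (see above); reduced-width replicas use the
  regular doubling pattern instead.
* The exact (L, W) values of the three contrast windows are standard
  literature values, not independently verified against the source
  figures; they are configuration, not constants.
* Training is pure-R/BLAS plus compiled convolution kernels: adequate for
  desk-scale phantoms, far from GPU speed; full-resolution clinical
  training is out of scope.
* NIfTI axis order is taken as stored; no re-orientation from the
  sform/qform codes is attempted beyond reading voxel spacing.
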