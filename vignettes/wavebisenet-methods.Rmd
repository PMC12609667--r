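---
title: "Wavelet-based bilateral segmentation of nanowire micrographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based bilateral segmentation of nanowire micrographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transmission electron micrographs of one-dimensional nanowires (here,
self-assembled peptide fibers) show dark, slender, curvilinear objects on a
brighter, blurred, noisy background. The fibers appear either dispersed with
incidental overlap or as dense entangled networks, and their boundaries are
soft. Segmenting such structures pixel-wise is hard for threshold-based
pipelines and is the task this package addresses with a bilateral
convolutional network, `wavebisenet`.

A bilateral segmentation network keeps two parallel branches: a shallow
**spatial path** at high resolution that preserves fine detail, and a deep
**context path** (a ResNet-18 topology) that captures semantics at coarse
resolution. The two meet at 1/8 of the input resolution in a feature fusion
module (FFM), and the fused map is upsampled 8x back to the input grid. The
variant implemented here replaces the spatial path's three stride-2
convolutions with **dual wavelet convolution modules** (DWCM) and the
bilinear upsamplers of the 1/32 context branch and the output head with
**flexible upsampling modules** (FUM). Both replacements are independently
switchable, giving the four-variant ablation grid
(`bisenetv1`, `bisenetv1+dwcm`, `bisenetv1+fum`, `wavebisenet`).

## Haar analysis and synthesis

Downsampling by discarding pixels (stride-2 convolution) aliases the thin,
high-frequency structures that carry most of the signal here. The DWCM
instead decomposes a feature map with the 2-D Haar wavelet: four 2x2 kernels
with stride 2 produce an approximation band `LL` and horizontal / vertical /
diagonal detail bands `LH`, `HL`, `HH`, each at half resolution. We scale all
four kernels by 1/2, which makes the family orthonormal: analysis followed by
synthesis is exactly the identity, subband energy equals input energy, and
the synthesis operator is simply the transpose of the analysis operator (the
printed kernel entries are the +/-1 sign patterns; the normalization makes
the inverse in the extraction block exact rather than inflating magnitudes
2x per level). The kernel size is 2x2 with stride 2 — pointwise (1x1)
convolutions appear only in the channel-mixing stages around the transform,
since 1x1 kernels cannot realize the Haar sign patterns.

Within a decomposition, no padding is needed because stride-2 2x2 kernels
tile an even-sized input exactly; odd inputs are edge-replication padded
first (`pad_even()`). Only levels 1 and 2 are supported — the cascade the
architecture uses — and the wavelet kernels are fixed (not trained): they
implement an exact transform, and training them would forfeit the
perfect-reconstruction identity the extraction block relies on.

The DWCM has two stages:

1. **Downsampling block** — Haar analysis, channel-wise concatenation of the
   four subbands (4C channels at half resolution), then 1x1 convolution +
   batch norm + ReLU down to the stage width.
2. **Extraction block** — a second analysis of the fused map: the level-1
   subband stack is mixed by a 1x1 convolution; the level-1 approximation is
   analyzed again (level 2) and mixed by its own 1x1 convolution; the level-2
   result is synthesized back to the level-1 grid and *added into the
   approximation slot*; a final synthesis returns to the block grid, and a
   linear 1x1 convolution expands to 4x the stage width before a 1x1
   conv-BN-ReLU projection. Each level is mixed by its own convolution
   (dimensional consistency forces this reading — the level-1 and level-2
   grids differ by a factor 2), and the two levels are merged by cascaded
   synthesis because their coefficients live on different grids.

## Dynamic upsampling

The FUM generalizes bilinear upsampling. Two 1x1 convolutions predict, for
each coarse position, channel group and fine sub-position, a 2-vector of
sampling offsets gated as `0.5 * sigmoid(a(x)) * b(x)` — an input-conditioned
range gate with a fixed cap of 0.5 coarse pixels. A pixel-shuffle remaps the
`2 g s^2` offset channels to the fine grid, the offsets are added to the
regular half-pixel sampling grid, and the input is sampled bilinearly at the
displaced positions (normalized [-1, 1] coordinates, border clamped). A 1x1
conv-BN-ReLU fuses channels afterwards. Defaults: `g = 4` channel groups
(reduced to 2 or 1 when the channel count is not divisible), `s = r` the
scale factor. The offset-producing convolution `b` is zero-initialized, so an
untrained FUM *is* bilinear upsampling; offsets grow only as training finds
them useful. The cap is a configuration constant, not a trained parameter.

The final x8 head applies the FUM to the fused `Cf`-channel features
(offsets predicted at the 1/8 feature grid) and classifies at full
resolution with a 1x1 convolution. Running the upsampler on 2-channel class
scores instead would push logits through the tail's ReLU, clamping them at
zero; the baseline (`bisenetv1`) keeps the standard order — classify at 1/8,
bilinear x8 on the scores.

## Network assembly

For a 512x512 input the spatial path runs 3 -> 64 x 256^2 -> 128 x 128^2 ->
256 x 64^2. The context path computes ResNet-18 features at 1/4 ... 1/32
(128^2 ... 16^2), applies channel attention (ARM: global average pool, 1x1
conv, BN, sigmoid) at 1/16 and 1/32, adds a global-pooling context vector
onto the 1/32 branch, and brings both branches to 1/8 (the 1/32 branch via
FUM x4 or bilinear x4 depending on the variant). FFM concatenates spatial
and context features, mixes with a 3x3 conv-BN-ReLU to `Cf = 256` channels
(the fused width is not printed anywhere; 256 matches the spatial-path
output and is configurable), and applies residual channel attention
`h + h * w`. Auxiliary supervision heads from the original bilateral recipe
are omitted (nothing in the training recipe uses them). The backbone is
built in-repo and He-initialized; pretrained weights can be loaded from a
checkpoint file but are never required or downloaded. `width_mult` scales
every channel width (rounded to multiples of 4, minimum 4) for desk-scale
experiments. Argmax ties in `predict_mask()` resolve to the lowest class
index, i.e. background — a determinism convention.

## Training objective and recipe

The loss is `0.5 * CE + 0.5 * weighted Dice`, both computed from the same
logits. Dice class weights default to inverse per-batch class frequency
(Laplace-smoothed so an absent class cannot produce an infinite weight),
normalized to sum 1 — nanowire pixels are rare, and plain macro Dice would
under-weight them; `class_weighting = "none"` gives macro Dice. The
smoothing constant is `1e-6`, preventing 0/0 on empty classes. Cross-entropy
itself is unweighted by default. The published recipe is followed: Adam with
learning rate 0.01 and betas (0.99, 0.99) (as printed, although beta1 = 0.99
is unusually high), L2 weight decay 0.001 folded into the gradient, batch
size 16, He initialization, inputs scaled to [0, 1], no augmentation, and a
reduce-on-plateau schedule halving the learning rate; the plateau monitor is
validation mIoU (maximized) with patience 10 epochs — the monitored quantity
and patience are not printed, and mIoU is the headline metric, so it is the
natural monitor. The best checkpoint is the highest-validation-mIoU epoch.

**Batch-norm inference statistics.** Standard exponential running averages
(momentum 0.1, eps 1e-5) lag the weights badly in short runs: 30 epochs x 9
minibatches is only ~270 updates while Adam at lr 0.01 with beta1 0.99 moves
the feature distributions quickly, and the attention-branch BNs see just N
values per update. In early experiments inference-mode predictions collapsed
to all-background while training-mode predictions were accurate. We
therefore re-estimate the population statistics after weight updates by
averaging batch statistics over up to four training minibatches (cumulative
average, momentum 1/k) before each validation pass — this is the original
batch-normalization prescription for inference statistics, of which the
exponential average is a long-run approximation. Inference still uses the
stored running statistics.

## Metrics and model comparison

All metrics derive from a pixel confusion matrix `n[i, j]` (reference class
i, predicted class j): per-class IoU and its class mean (mIoU; zero-union
classes are excluded from the mean with a warning), overall accuracy,
precision / recall / F1 of the foreground class (macro-F1 available via a
flag), and Cohen's kappa `(po - pe) / (1 - pe)`. The test set accumulates
into one global matrix (micro averaging) — matching the single aggregate
matrix reported for this task — while per-image mIoU lists are kept for the
bootstrap. Note a documented inconsistency in the source material: metrics
recomputed from the published aggregate confusion matrix (accuracy ~ 0.9055,
mIoU ~ 0.799, F1 ~ 0.840) do not equal the published headline table
(89.95 / 77.59 / 87.22); the implementation trusts the formulas and the
tests assert the divergence rather than reconciling it.

Model comparison resamples *images* (not pixels), paired across models, with
replacement — 10,000 resamples by default — and reports 95% percentile
intervals for each model's mean score and for the paired difference; the
difference is significant when its interval excludes zero.

## Synthetic data and the annotation pipeline

The generator renders smooth random-heading walks (heading increments
`Normal(0, curvature)`, unit pixel steps, lengths 0.5-1.2 of the longer image
side) with a hard circular brush into a binary mask — no anti-aliasing, so
masks are exactly binary; all image-side softness comes from the blur. The
image is a bright field (level 170) with a random linear illumination ramp
(amplitude 15), wire pixels set to level 50, Gaussian blur (sigma 1), and
additive Gaussian noise (sd 8), clipped to 8 bits. The `dispersed` regime
draws 3-8 fibers, `network` 15-30 with frequent crossings. Each sample is a
pure function of its seed. What this emulates: geometry (thin curvilinear
dark objects, entanglement), contrast polarity, blur and noise of TEM
micrographs. What it does not: electron-optical contrast physics, carbon-film
texture, beam damage, or annotation error — so green tests certify the
machinery, not real-data performance at the published scale.

The annotation pipeline follows the printed procedure literally: 3x3 median
filter, conversion to HSV, initial mask from the dual thresholds `S < 40`
and `V < 90` (0-255 scales), one opening, two closings, and one pixel of
dilation, all with a full 3x3 structuring element. Grayscale images are
replicated to three channels, which makes saturation identically zero — the
value threshold then governs; both thresholds are applied anyway, faithfully
to the procedure and to its degeneracy. Morphology ignores out-of-image
neighbours (erosion acts as if padded with foreground, dilation with
background), so a uniform mask is a fixed point of both — a border
convention the hand-stepped test oracles share. The dataset protocol splits
at the source-image level 7:2:1 *before* cropping into a non-overlapping
patch grid (no leakage across splits); the default patch size of 512 matches
the network input.

## Desk-scale study sizes

The reference micro-study (`micro_benchmark()`) trains the width-0.25
network on 200 synthetic 64x64 dispersed-fiber images (2-4 fibers of width
3-5 px, blur 0.8, noise 5), split 140/40/20, for 30 epochs on one CPU —
minutes, not GPU-days. The test suite additionally trains width-0.125
networks on 32x32 images for a handful of epochs. These sizes were chosen as
the smallest at which the network's behaviour is still recognizably the
full-scale one (all 32x downsampling stages active, fibers a few pixels
wide, class imbalance ~10:1). Reproducing the published full-scale numbers
would require the external TEM dataset and ~300-epoch GPU training and is
out of scope here.

## Numerical choices and degenerate inputs

* Bilinear sampling uses half-pixel centers, normalized [-1, 1] coordinates
  and border clamping; offsets are expressed in coarse-pixel units and
  converted by `2/size`. These conventions are fixed bit-exactly so the
  zero-offset FUM equals plain bilinear upsampling to machine precision
  (up to the BN epsilon in its tail).
* Inputs with spatial dimensions not divisible by 32 are rejected with the
  required padded size stated; odd inputs to the wavelet operators are
  edge-replication padded.
* Degenerate metric cases: zero-union classes are excluded from mIoU with a
  warning; zero-denominator precision/recall/F1 and the single-class kappa
  return 0 with a `degenerate` flag.
* Softmax, cross-entropy and the log-sum-exp are computed with max
  subtraction; probabilities are floored at 1e-300 inside the log.
* Checkpoints serialize the configuration plus every weight and batch-norm
  buffer; save -> load -> evaluate is bitwise reproducible.

## Known limitations

* The engine is CPU-only and sized for desk-scale experiments; full-width
  512x512 training is out of reach (a full-size *forward* pass runs in
  seconds, training would take days).
* The synthetic phantom's simplifications above mean measured IoUs here do
  not predict real-TEM IoUs.
* Only binary (background / nanowire) segmentation is exercised, although
  the metrics and network support `num_classes > 2`.
* The SAM-assisted manual mask-correction step of the original annotation
  protocol depends on an external foundation model and is not reproduced;
  the threshold + morphology stage is.
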