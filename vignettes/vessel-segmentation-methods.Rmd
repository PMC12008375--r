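---
title: "Multi-path vessel segmentation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-path vessel segmentation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fundusnet)
```

## The problem

Retinal fundus photographs show the vascular tree of the eye, whose geometry
(vessel calibre, branching angles, tortuosity) carries diagnostic information
for diabetic retinopathy, hypertension and related conditions.  Automating
vessel segmentation is hard for three reasons: vessels span a wide range of
widths within one image, the thinnest vessels sit at very low contrast against
an unevenly illuminated background, and pathological structures (exudates,
haemorrhages) look locally vessel-like and provoke false positives.

`fundusnet` implements a multi-path U-shaped convolutional network aimed at
exactly these failure modes, together with everything needed to exercise it
end to end on one CPU: a synthetic fundus generator, the standard
grayscale/normalisation/CLAHE preprocessing pipeline, sliding-window patching
with overlap-averaged stitching, a seeded training loop, and pixel-level
evaluation (accuracy, sensitivity, specificity, F1, ROC/AUC).

## The network

The model (`buildNetwork()` over a `networkSpec()`) has three cooperating
parts.

**Dual branches over a shared encoder.**  A 5-level *structural* branch
captures the vessel skeleton; a 3-level *texture* branch, whose encoder
stages are literally the same parameter objects as structural stages 1–3
(storage identity, not copies), specialises in fine boundary detail.  The
first encoder stage is a 3×3 convolution with F output channels followed by a
residual block; deeper stages are 2×2 stride-2 downsampling convolutions
followed by a cascade dilated convolution module.  Channel widths double per
level from the base width F (defaults F = 16: 16/32/64/128/256).  Decoders
upsample with 3×3 stride-2 transposed convolutions (output padding 1, exact
spatial doubling).

**Cascade dilated convolution module (CDCM).**  Each deeper encoder stage
contains three densely connected layers; layer *l* is a 1×1
conv/norm/rectifier bottleneck (CBR) followed by a 3×3 dilated
conv/norm/rectifier/dropout stage (CBRD) with dilation rate 1, 3 or 5,
producing k new feature maps.  Layer *l* consumes the concatenation of the
block input and all previous layers' new maps, so its input width is
F + (l − 1)k.  The input and the three outputs — four feature groups — are
concatenated and fused by a 1×1 projection back to F channels.  A cascade of
3×3 convolutions at rates (1, 3, 5) yields a 19×19 receptive field
(1 + 2·(1+3+5)), which `cdcmReceptiveField()` verifies by gradient probing.

**Probability-distribution attention (PDA).**  At every decoder skip
junction, shallow logits F′ (a learned 1×1 head on the upsampled features)
are softmax-mapped to per-pixel class probability planes.  Each plane
reweights the encoder skip features element-wise; the C attended stacks are
concatenated and projected by a learned 1×1 kernel K back to the deep width;
the result is added to the deep features (`pdaForward()`).  The intent is to
keep low-level detail from being washed out by deep semantics: the vessel
plane of a coarse prediction amplifies skip activations where vessels are
plausible.

**Cascaded refinement as boosting.**  The source image and both branch
probability maps are concatenated and passed through a 4-level U-shaped
refinement module, with skip connections from the structural decoder into the
refinement encoder at matching scales.  This is the architectural realisation
of stagewise refinement: later stages consume earlier stages' predictions and
learn to correct their residual errors.  The literal functional
gradient-boosting formulation — residual fitting by least squares plus scalar
line search for each stage's expansion coefficient — lives in `fitBoost()` /
`boostPredict()`, where it is tested on small regression problems.  How the
boosting equations would parameterise the upscaling blocks directly is not
defined beyond this cascaded-refinement reading, and we deliberately do not
guess further.

**Loss.**  Training minimises
γ·CE(refined) + (1 − γ)·Σ β_d·CE(decoder_d), with β = (0.3, 0.3, 0.4) over
the lower, middle and output decoder taps (upsampled to input resolution by
nearest neighbour) and γ = 0.5.  The cross entropy is the binary-style form
accumulated over both categories; we average over categories, pixels and
batch so the loss is resolution-independent, and clamp probabilities at 1e-7
before the logarithms.  The per-decoder and aggregated losses are both
implemented per-pixel; the granularity relationship between the two written
forms is ambiguous, and per-pixel is the only reading consistent with a
fully convolutional model.

## Interpretation choices worth knowing about

Several architectural details were genuinely open and resolved as follows
(each is exposed to tests, so a different reading would fail loudly):

- "Sixteen 3×3 convolutions" in the first encoder stage is read as one 3×3
  convolution with 16 output channels, not 16 stacked layers — the standard
  U-Net reading, consistent with doubling widths per level.
- The three dilated convolutions are a *dense cascade* (one CBRD per rate,
  each consuming everything before it), not three parallel paths; only this
  reading produces both the F + (l−1)k channel arithmetic and the 19×19
  receptive field.
- In the attention formula F̄ = F ⊕ ((soft(F′)·f_i) ⊗ K), the kernel K is a
  learnable 1×1 convolution, ⊕ is element-wise addition and ⊗ is convolution
  application — the only shape-consistent reading.  F′ is the shallow-branch
  logits produced by a 1×1 head on the decoder features.
- The attention class set ("trunk, branches, terminal points, etc.") is
  collapsed to the model's C output classes (default 2, vessel/background),
  since the supervision is binary masks.
- PDA sits inside each upscaling block: after the transposed convolution and
  before the stage's convolutions, acting on the deep features and the skip
  features at that scale.  A sentence describing encoder stages as "CDCM
  followed by PDA" is not implementable as written (in the encoder there are
  no shallow logits or skip features for PDA to consume), so attention is
  applied in the decoders only.
- Deep supervision taps the structural decoder at 1/4 resolution ("lower"),
  1/2 resolution ("middle") and full resolution (the branch output).
- Batch normalisation inside CBR/CBRD uses running statistics frozen in
  evaluation mode; dropout rate defaults to 0.2 (unstated in the source
  design; a common value for dense blocks).

## The synthetic generator

Real benchmark datasets cannot be bundled, so `generateSample()` emulates the
statistical structure that makes the task hard.  Vessel trees grow by a
biased random walk with bounded curvature from root stems near the
field-of-view rim; branches split dichotomously with probability 0.02 per
step, widths shrinking by `branchDecay` (default 0.72) per level from stems
of 3.6–6 px down to sub-pixel tips; each tree has a centreline budget of
3.5·max(H, W) px so that density stays bounded.  Vessels render dark with
width-dependent contrast (thin tips are faint — the stated challenge), over a
background with a linear illumination drift (peak-to-peak 0.25), Gaussian
noise (sd 0.03), and bright/dark elliptical lesion blobs that are *not* in
the ground truth, exercising false-positive suppression.

Under the default configuration the vessel-pixel fraction of the field of
view lies in [0.03, 0.20] (measured ≈ 0.05–0.14 across seeds, mean ≈ 0.10 by
the bundled checks), and well
over 10% of vessel pixels lie in branches at most 2 px wide.  What the
generator does **not** emulate: colour (images are single-channel), the optic
disc, the central vessel reflex, camera vignetting and JPEG artefacts.
Passing tests on synthetic data therefore demonstrate that the architecture,
losses, training loop and metrics behave as specified — not clinical-grade
performance on real retinas, which requires the real datasets and full-scale
training.

## Preprocessing, patching, training

Preprocessing is grayscale conversion (BT.601 weights), normalisation
(z-scoring followed by an affine rescale to [0,1], making the result
invariant to affine intensity changes; min–max as an alternative), then CLAHE
(clip limit 2.0 on 8-bit-equivalent histograms, 8×8 tiles — the community
defaults for fundus work).  A constant image is normalised to all-0.5 and
passes CLAHE unchanged, documented degenerate conventions.

Training samples 64×64 patches whose centres lie inside the FOV, augmented by
quarter rotations (counter-clockwise convention), flips and optional scale
jitter applied jointly to image and mask (mask re-binarised by nearest
neighbour).  Whole-image prediction uses an edge-snapped sliding grid
(stride = patch/2 at test time) and per-pixel averaging of overlapping
predictions; edge snapping avoids zero-padding artefacts in the stitched
maps.  The published hyperparameters are the defaults: learning rate 5e-4,
batch 6, 20 epochs, early stopping after 10 epochs without a new best
validation loss ("best weights" = lowest validation loss; switchable in
principle to validation F1).  The optimizer is adaptive moment estimation
(Adam) with standard moments — none is named in the source design, and Adam
is the community default at this learning rate.  All randomness flows
through R's Mersenne-Twister stream, so `setGlobalSeed()` makes runs exactly
reproducible.

## Evaluation

Metrics are computed inside the FOV only (standard practice for fundus
benchmarks; toggleable).  Dataset-level accuracy/sensitivity/specificity/F1
pool pixel counts over images (micro-averaging); per-image F1 values are
reported alongside.  AUC comes from a threshold sweep over all distinct
scores with trapezoidal integration, which equals the pairwise concordance
probability with ties credited one half; pooled pixels (rather than
per-image averaging) were chosen for the dataset AUC.

## Problem sizes used by the tests and the acceptance script

The bundled checks run a deliberately small instantiation chosen as the
smallest configuration that still exercises every module: base width F = 8
with growth k = 8 (the architecture is unchanged; only widths shrink),
24 synthetic 128×128 images (16 train / 4 validation / 4 held out),
120 patches per epoch for two epochs, and a 200-step single-patch overfit.
Under these conditions the held-out AUC is typically 0.84–0.92 and the
overfit Dice 0.97–0.99 (seeds 1, 2, 7, 13); the acceptance script recomputes
both from scratch at whatever seed it is given.

## Known limitations

- The compute engine is a compact reverse-mode tape over im2col-based
  convolutions — adequate for the bundled problem sizes, but not a
  performance match for a GPU framework at benchmark scale.
- Transfer learning (encoder initialisation from natural-image pretraining)
  is out of scope; `loadCheckpoint()` accepts externally supplied weights,
  which is the supported hook.
- The auxiliary third-party enhancement step sometimes placed before the
  network is represented by an optional no-op hook; it is an external method
  and intentionally not reimplemented.
- Published benchmark figures on DRIVE/STARE/CHASE_DB1 are not reproducible
  here by design: they need the real images and full-scale training.
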