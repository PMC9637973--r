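---
title: "Guided non-local attention segmentation of spinal ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided non-local attention segmentation of spinal ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Scoliosis screening with freehand 3-D ultrasound needs, as its first stage,
a reliable segmentation of bony features — spinous processes, laminae,
transverse processes, ribs — in 2-D B-mode frames. Bone surfaces appear as
bright arcs with a dark acoustic shadow beneath them, embedded in
multiplicative speckle at low signal-to-noise ratio. Plain encoder–decoder
CNNs see only local neighbourhoods; this package implements a network whose
central mechanism is *guided non-local attention*: long-range feature
aggregation in both the spatial and the channel domain, steered by a
multi-scale guidance map that carries shallow edge detail the deep layers
have lost.

## Architecture

The forward pass is

1. **Encoder.** A ResNet-style convolutional encoder produces four stage
   outputs at strides 4, 8, 16 and 32 (basic residual blocks for the
   `"tiny"`/18 depths, bottleneck blocks for 50/101). There is no batch
   normalization: training here is small-batch on CPU, so the network relies
   on He fan-in initialization and identity residual paths instead.
2. **DASPP.** Dense atrous spatial pyramid pooling on the deepest stage:
   dilated 3×3 branches at increasing rates, each branch seeing the input
   concatenated with all earlier branch outputs, finally projected 1×1 to
   the working channel width. This widens the receptive field without
   further downsampling. A dilation rate larger than the feature map is
   rejected as a misconfiguration.
3. **Multi-scale fusion.** Every stage is resized bilinearly to stride 4,
   concatenated, and projected 1×1 into the fusion map `F1` — shallow detail
   plus deep semantics. A further 1×1 projection and bilinear resize of `F1`
   yields the guidance map `FG`, shape-matched to the attention input.
4. **Spatial-wise guidance block.** With `FX` the (resized) DASPP output,
   three 1×1 convolutions give query/key/value maps α, β, γ. Flattened to
   `c × hw`, the row-softmax of `αᵀβ` is the position-similarity matrix
   `SW` (hw × hw); two more 1×1 convolutions on `FG` give the guidance
   similarity `MG` the same way. Their elementwise product, renormalized by
   a row softmax, is the guided similarity `MS`; the output is
   `Y = reshape(MS·γᵀ) + FX`.
5. **Channel-wise guidance block.** The c × c channel similarity `MZ` is the
   row-softmax of `ŶŶᵀ`. The guidance map passes through a
   squeeze-and-excitation gate — global average pooling to channel
   statistics λ, two fully connected layers with a ReLU between and a
   sigmoid on top, giving per-channel coefficients `vc ∈ (0,1)` that rescale
   `FG` — and the gated map yields `M̂G` analogously. `MQ` is the row-softmax
   of `MZ ⊙ M̂G`, and the output is `Z = reshape(MQ·Ŷ) + Y`.
6. **Head.** A 1×1 convolution over `Z` concatenated with `F1` (resized to
   the attention resolution), bilinear upsampling to the input size, and a
   sigmoid give the foreground probability map.

Every similarity matrix is row-stochastic by construction: each query row is
a probability distribution over keys. The test suite verifies this, the
scalar-oracle equivalence of both blocks, and the degenerate closed forms
(a single spatial position gives `Y = γ(FX) + FX`; a single channel gives
`Z = 2Y`; zeroed gate layers give `vc ≡ 0.5`).

### Why the head fuses `Z` with `F1`

The attention blocks *redistribute* feature content; they do not create
spatial detail. The value map γ is computed from the DASPP output, whose
content originates at stride 32. At small image sizes (the deepest stage of
a 64×64 frame is 2×2) the value palette is a four-corner bilinear ramp, and
the only route for fine localization would be an intricate coordination of
the doubly-softmaxed guidance similarities — a path we found empirically
unlearnable at a fixed small-step budget: optimization stalls at the
base-rate constant prediction. Concatenating the stride-4 fusion map into
the head restores a direct gradient path for fine detail while the guidance
blocks refine it; this is the standard resolution of the same problem in
multi-scale segmentation heads. At clinical frame sizes (640×480, deepest
stage 20×15) the coarse path carries real content and the fusion is simply
complementary.

### Key configuration values

| parameter | default | meaning |
|---|---|---|
| `encoder_depth` | 101 (`"tiny"` for tests) | encoder depth; bottleneck blocks for 50/101 |
| `base_channels` | 64 (24 tiny) | width of the first stage |
| `daspp_rates` | 3, 6, 12, 18 (1 tiny) | dilation rates of the dense pyramid |
| `attention_channels` | 64 (48 tiny) | working width of DASPP/fusion/attention |
| `attention_stride` | 16 (4 tiny) | resolution at which attention runs; cost is quadratic in `hw` |
| `se_reduction` | 16 (4 tiny) | squeeze-excitation bottleneck ratio |
| `head_threshold` | 0.5 | probability cutoff for masks (ties are foreground) |

The tiny configuration runs attention at stride 4 because at stride 16 a
64×64 frame collapses to a 4×4 attention grid that cannot express thin arc
masks; its DASPP rate is 1 because the deepest 2×2 stage admits no larger
dilation.

## Training and evaluation

Training minimizes the mean per-pixel binary cross-entropy between the
probability map and the binary mask (computed from logits in a numerically
stable form; the per-pixel mean makes loss magnitudes independent of image
and batch size). Optimization is Adam with learning rate 0.001, moments
(0.9, 0.999), batch size 8, 50 epochs by default; no learning-rate
schedule, weight decay, or augmentation (hooks exist in the configuration
but default off). Everything — initialization, shuffling, the optional
holdout split — derives from one seed, so runs are bit-reproducible.

Evaluation uses Dice, Jaccard, precision and recall with the conventions:
if both masks are empty all four are 1; if exactly one is empty all four
are 0. Metrics are computed per image and averaged within a fold (pooled
pixel counts would weight large structures more; the per-image average is
the choice here and is what the harness reports). k-fold cross-validation
assigns samples to folds by a seeded shuffle and contiguous chunking,
trains on each complement, and reports per-fold means plus the across-fold
mean ± population standard deviation, conventionally printed in percent.
The harness takes any model factory satisfying the predictor contract, so
ground-truth oracles and constant baselines validate the protocol itself.

## Dense-CRF refinement

At test time the probability map can be refined by mean-field inference on
a two-label fully connected CRF: unary potentials are the negative log of
the clamped network probabilities; pairwise potentials are a spatial
Gaussian kernel (σ = 3 px, weight 3) plus a bilateral position×intensity
kernel (σxy = 30 px, σI = 13 gray levels, weight 5) under Potts
compatibility, five iterations. The implementation is self-contained: for
images up to 6400 pixels the exact dense kernel is materialized; larger
images use truncated-window message passing (radius 3σ capped at 12 px, a
documented approximation). Marginals are renormalized every iteration, and
zero pairwise weights reduce refinement to the identity exactly. On thin
structures a strong Potts smoothing erodes as well as denoises, so the
refinement is validated as "does not decrease Dice on a corrupted map",
not as a guaranteed repair.

## The phantom generator

The paired-image generator stands in for clinical data. It emulates three
gross properties of paraspinal B-mode frames: bright, downward-opening
circular-arc bone echoes (intensity 0.9, thickness 5 px, 3 arcs by
default); dark acoustic shadows (every pixel below an arc in the same
column attenuated by 0.35); and unit-mean gamma multiplicative speckle
(shape 4) over a 0.25 background, clipped to [0, 1]. Arc placement is
re-drawn until the foreground fraction lies in (0.01, 0.2). Each sample is
a deterministic function of `(seed, index)` with its own derived stream, so
datasets are order-independent and parallel-safe. The default geometry is
640×480 like clinical frames; tests use 64×64.

What the phantom does *not* model: wave propagation, probe geometry,
reverberation and mirror artifacts, depth-dependent gain, anatomical layout
of vertebrae, and inter-patient variation. Tests passing on phantoms
therefore demonstrate that the architecture, optimization and harness work
— that the network can extract bright-arc structure from speckle and
shadows — not that clinical-grade accuracy transfers to real scans, whose
headline numbers were measured on data that is not available here.

## Numerical choices

- Feature maps are `(channels, height, width, batch)` arrays; flattening to
  `c × hw` is column-major (depth index fastest), R's natural order; all
  transposes in the attention algebra follow from this one convention, and
  every tested invariant is convention-independent.
- Softmax is always over keys (the last index of the similarity product),
  with max-subtraction for stability.
- BCE clamps predictions to `[1e-7, 1 - 1e-7]`; the CRF clamps at `1e-6`.
- The automatic-differentiation core (reverse-mode, define-by-run, im2col
  convolutions lowered to BLAS) is validated against central finite
  differences; the attention blocks additionally against scalar double-loop
  oracles written independently of the vectorized code.
- Probability PNGs quantize by `round(p * 255)` (R's round-half-to-even, so
  0.5 stores as gray 128); masks binarize at 128 of 255 on load.
- Images with sides not divisible by 32 are reflectively padded and the
  output cropped back.
- The head bias starts at −2 (a sparse-foreground prior) so early steps are
  not spent collapsing to the background rate; the squeeze-excitation
  bottleneck bias starts at 0.1 so its ReLU is active at initialization.

## Problem sizes in the test suite

The suite is sized for a single CPU: attention oracles run on 3×3×4 blocks;
row-stochasticity on 100 random draws; the training-capacity check fits 16
seeded 64×64 phantoms for 200 Adam steps with the tiny configuration and
asserts a training Dice of at least 0.85; cross-validation protocol checks
use 8 phantoms at 32×32 with oracle predictors; CRF checks use one 64×64
frame with 8% salt-and-pepper corruption.

## Known limitations

- Depths 50/101 are faithful in structure but impractically slow to *train*
  in pure R; they are intended for forward-pass and architectural use. The
  tiny configuration is the supported training path at desk scale.
- The attention cost is quadratic in `hw`; memory-efficient attention is
  out of scope by design — `attention_stride` is the lever.
- The CRF parameters are literature defaults, not learned; the truncated
  window for large images under-weights very long-range bilateral
  interactions.
- Single foreground class: per-structure labelling (spinous vs. transverse
  process) is out of scope.
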