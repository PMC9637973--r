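# ugbnet

Automatic segmentation of bony features — spinous processes, laminae,
transverse processes, ribs — in 2-D B-mode spinal ultrasound frames, the
first stage of ultrasound-based scoliosis assessment. Bone surfaces show as
bright arcs over dark acoustic shadows, buried in multiplicative speckle;
plain convolutional segmenters see only local context and miss long-range
structure.

The core of the package is a guided non-local attention network:

- a ResNet-style encoder (strides 4–32) with **dense atrous spatial pyramid
  pooling** on the deepest stage;
- a **multi-scale fusion map** `F1` (all stages resized to stride 4,
  concatenated, projected) that combines shallow detail with deep semantics;
- a **spatial-wise guidance block**: with query/key/value maps α, β, γ from
  1×1 convolutions of the feature map `FX`, the position similarity is
  `SW = softmax(αᵀβ)` (hw×hw, row-stochastic); the guidance map `FG`
  (projected from `F1`) yields `MG` the same way; the guided similarity is
  `MS = softmax(SW ⊙ MG)` and the output is `Y = reshape(MS·γᵀ) + FX`;
- a **channel-wise guidance block**: channel similarity
  `MZ = softmax(ŶŶᵀ)` (c×c), a squeeze-and-excitation gate
  `vc = σ(P₂ φ(P₁ λ))` on `FG` giving `M̂G`, the guided similarity
  `MQ = softmax(MZ ⊙ M̂G)`, and `Z = reshape(MQ·Ŷ) + Y`;
- a 1×1 prediction head over `Z` fused with `F1`, bilinear upsampling, and
  a sigmoid.

Training is Adam (lr 0.001, batch 8) on mean per-pixel binary
cross-entropy; evaluation is Dice / Jaccard / precision / recall under
k-fold cross-validation reported as mean ± sd percent; an optional
fully connected CRF (mean-field, Gaussian + bilateral kernels) refines
probability maps at test time. Everything runs on a reverse-mode
automatic-differentiation core written in R (im2col convolutions lowered to
BLAS), validated against finite differences and scalar oracles. A
speckle-phantom generator produces paired synthetic frames and bone masks
(arcs + shadows + gamma speckle) so the whole pipeline is testable without
clinical data.

## Worked example

```r
library(ugbnet)

# 16 paired 64x64 phantoms: bright bone arcs, speckle, acoustic shadows
params <- phantom_params(height = 64, width = 64, seed = 11)
ds <- generate_dataset(params, 16)
mean(ds[[1]]$mask)                       # foreground fraction: 0.032

# small network, short seeded training run (200 Adam steps)
mc <- tiny_model_config()
tc <- train_config(epochs = 100, batch_size = 8, seed = 5,
                   holdout_frac = 0, max_steps = 200, eval_every = 50)
fit <- train_ugbnet(ds, mc, tc)
dplyr::filter(tidy(fit), !is.na(dice))
#>   epoch   loss  dice
#> 1    50 0.0252 0.859
#> 2   100 0.0180 0.905

# predict one frame, threshold, score
s <- ds[[1]]
prob <- ugbnet_forward(s, mc, fit$weights)
seg_metrics(predict_mask(prob, 0.5), s$mask)
#>    dice jaccard precision recall
#> 1 0.911   0.837     0.929  0.894
```

The training Dice of 0.905 says the architecture can fit its target signal
at desk scale. CRF refinement (`refine_crf(s, prob, crf_params())`) is
aimed at noisy maps: on a map corrupted by salt-and-pepper flips it raises
Dice (0.47 → 0.60, `scripts/acceptance.R --seed 1`), while on an already-clean map of thin
arcs the default Potts smoothing trades recall for precision — see the
methods vignette.

The cross-validation harness accepts any model factory; a ground-truth
oracle validates the protocol:

```r
cv <- cross_validate(ds, mc, train_config(folds = 4, seed = 3),
                     model_factory = oracle_model_factory)
format_cv_table(cv)
#>   metric    value
#> 1 dice      100.0 ± 0.0
#> 2 jaccard   100.0 ± 0.0
#> 3 precision 100.0 ± 0.0
#> 4 recall    100.0 ± 0.0
```

A command-line interface wraps the same functions
(`inst/cli/ugbnet.R`, installed under `system.file("cli", "ugbnet.R",
package = "ugbnet")`):

```sh
Rscript inst/cli/ugbnet.R generate --out data/ --n 16 --seed 1 --height 64 --width 64
Rscript inst/cli/ugbnet.R train    --data data/ --out ckpt/model.rds
Rscript inst/cli/ugbnet.R predict  --model ckpt/model.rds --in data/ --out preds/ --crf
Rscript inst/cli/ugbnet.R evaluate --data data/ --pred preds/ --out metrics
Rscript inst/cli/ugbnet.R crossval --data data/ --out cv
```

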