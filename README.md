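# leafseg

Semantic segmentation of plant leaves and foliar disease lesions —
per-pixel classification of an image into **background**, **leaf** and
**disease** — for researchers studying disease quantification in field
imagery and for anyone who needs a fully self-contained, testable
segmentation stack in R.

Field images make this hard in two specific ways: lesions occupy a few
percent of the pixels (severe foreground/background imbalance), and
lighting gradients, water droplets and jagged leaf edges concentrate
errors exactly at lesion boundaries. The package implements a U-Net
variant built around those two problems:

* **Residual attention encoder blocks.** Each encoder stage combines a
  modified residual block (main path `F(x)` of two 3×3 convolutions, 1×1
  projection shortcut `g(x)`, output `F(x) + g(x)`) with a residual
  convolutional attention module: channel weights `P_c(T)` from pooled
  descriptors through a shared MLP, spatial weights `P_s(T′)` from a 7×7
  convolution over channel-pooled maps, fused as

  `T′ = P_c(T) ⊗ T`,  `T″ = P_s(T′) ⊗ T′`,  `O = T + T′ + T″`.

* **Dilated-pyramid bottleneck.** The deepest downsampling stage is
  replaced by three parallel 3×3 convolutions with dilation rates 6, 12
  and 18 plus a channel-setting 1×1 convolution, trading detail against
  context at three receptive-field scales.

* **Weight-compression loss.** Cross-entropy rescaled by an arctan
  modulation factor,

  `L(p, y=1) = −(1 − arctan p)^γ · log p`,
  `L(p, y=0) = −(arctan p)^γ · log(1 − p)`,

  with `arctan p ∈ (0, π/4)`; confident (easy) pixels are down-weighted so
  the rare disease class dominates the gradient. `γ = 0` recovers plain
  cross-entropy; the default operating point is `γ = 2`.

Around the model: a seeded synthetic leaf-scene generator with
controllable class imbalance and nuisance factors (lighting ramps,
specular droplets, jagged edges), an image/mask pipeline (paired
augmentation — flips, crop-and-resize, brightness 0.5–1.2×, contrast and
chroma 0.5–2.5×; stratified 6:2:2 splits), a confusion-matrix evaluation
suite (accuracy, per-class P/R/F1/IoU, mPA, mIoU, Cohen's κ), and a seeded
SGD training loop with ablation and γ-sweep harnesses. All network layers,
including backpropagation, are implemented in R + C++ in this package and
verified against finite differences — no deep-learning framework is
required.

## Worked example

```r
library(leafseg)

# 16 synthetic scenes, 64x64, ~30:1 leaf-to-lesion pixel imbalance
ds <- generate_dataset(16, scene_params(image_size = 64), seed = 7)
split <- split_dataset(ds$samples, seed = 1)

set.seed(1)
model <- build_model(network_config(base_channels = 8))
fit <- train_model(model, ds$samples,
                   train_config(learning_rate = 0.05, epochs = 25,
                                loss = "wc", gamma = 2, seed = 1),
                   split = split)

ids <- vapply(ds$samples, `[[`, "", "id")
ev <- evaluate_model(fit$model, ds$samples[match(split$test, ids)])
print(ev$report)
```

```
Class           IoU/%      R/%      P/%     F1/%
background      97.43    99.37    98.04    98.70
leaf            94.90    98.30    96.49    97.38
disease         19.92    20.88    81.25    33.23
accuracy 0.9743  mPA 0.7285  mIoU 0.7075  kappa 0.9442
```

Reading the numbers: after a short desk-scale run the abundant classes
are essentially solved (background/leaf IoU 97/95%), while the rare
disease class lags (IoU 20%, recall 21% at precision 81%) — the
class-imbalance problem the loss design targets; accuracy (97%) is
dominated by the majority classes, which is exactly why mPA, mIoU and κ
are reported alongside it. Longer budgets push disease IoU far higher
(the test suite trains to ~0.9 on held-out scenes in 30 epochs).

`summarize_architecture(model, input_size = 64)` prints the live shape
trace; with the default width (`base_channels = 64`) and a 512×512 input
it reproduces the reference channel plan — encoders 64/128/256/512,
bottleneck 1024×64×64 then 1024×32×32, decoders 512/256/128/64, output
3×512×512:

```
encoder stages: 4, decoder stages: 4
bottleneck dilation rates: 6, 12, 18
output channels: 3
  encoder1              8 x   64 x   64
  encoder2             16 x   32 x   32
  encoder3             32 x   16 x   16
  encoder4             64 x    8 x    8
  bottleneck          128 x    8 x    8
  bottleneck_pooled   128 x    4 x    4
  decoder1             64 x    8 x    8
  ...
  output                3 x   64 x   64
```

A thin command-line front end ships in `inst/cli/leafseg` with
subcommands `synth`, `expand`, `train`, `eval`, `ablate` and `sweep-gamma`.

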