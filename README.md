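# dermseg

Binary segmentation of skin lesions in dermoscopic images, built
around an attention-gated U-Net variant with two further
architectural extensions and a fully reproducible synthetic test bed.

Dermoscopic lesion segmentation is the entry point of automated
melanoma assessment: asymmetry, border irregularity and pigment
spread are all computed from the lesion boundary. The hard cases are
low-contrast lesions and images occluded by hairs. `dermseg`
addresses both ends of the problem:

* **Preprocessing** — hair removal by black-hat morphology
  (`closing(I) − I` with a 17 × 17 rectangular element), strict
  thresholding at `T = 50`, and fast-marching inpainting; bilinear
  resize and `[0, 1]` normalization; paired affine augmentation
  (rotation ± 30°, shifts ± 10 %, shear ± 0.2, zoom ± 40 %, flips).
* **Network** — a U-Net encoder–decoder (32/64-filter encoder blocks,
  128-filter bottleneck, 64/32-filter decoder blocks) with three
  switchable extensions:
  * *attention gates* on the skip connections,
    `α = σ(ψ(ReLU(θ(x) + φ(g))))`, gating the skip features;
  * an *order-statistics layer* at the bottleneck that appends the
    normalized per-pixel channel extremes
    `smallₖ/(largeₖ+ε)` and `largeₖ/(largeₖ+ε)` as two extra channels;
  * *iterative decoder feedback*: the decoder runs `T` passes and on
    pass `t > 1` concatenates the previous pass's block outputs
    (1 × 1-projected) into each decoder block; one pass reduces
    exactly to the feedback-free network.
* **Training** — hybrid loss `0.5·(1 − softDice) + 0.5·BCE`, Adam
  (lr 1e-4, β₁ 0.9, β₂ 0.999), batch 16, ≤ 150 epochs, learning-rate
  decay ×0.1 after 10 stalled epochs, early stopping after 15, best
  validation weights restored.
* **Metrics** — Dice, Jaccard (with the identity `IoU = D/(2−D)`
  asserted to machine precision), pixel accuracy, precision, recall,
  midrank ROC AUC, plus a five-configuration ablation harness.
* **Synthetic data** — seeded dermoscopic-like scenes (skin-tone
  background, one irregular darker lesion, optional 1–3 px hair
  strands) with exact ground truth, so the entire pipeline is testable
  offline.

The network layers (convolutions, batch normalization, pooling,
attention, the order-statistics layer, Adam, and the full backward
pass) are implemented in the package itself with RcppArmadillo
kernels; there is no deep-learning framework dependency.

## Worked example

```r
library(dermseg)

## a reproducible synthetic scene with hairs and exact ground truth
spec  <- lesionSpec(center = c(48, 48), semiAxes = c(18, 14),
                    irregularity = 0.2, contrast = 55)
bg    <- genBackground(96, 96, seed = 7)
mask  <- genLesionMask(96, 96, spec, seed = 8)
scene <- renderScene(bg, mask, spec, hair = hairSpec(nStrands = 3), seed = 9)

## hair removal: black-hat detection at T = 50, then inpainting
resp  <- blackHat(rgbToGray(scene$image), c(17, 17))
hairs <- hairMask(resp, 50)
cat("hair pixels detected:",
    round(100 * sum(hairs[scene$hairTruth == 1] > 0) / sum(scene$hairTruth), 1),
    "%\n")
#> hair pixels detected: 99.6 %
clean <- inpaintHair(scene$image, hairs, radius = 3)

## train a reduced model on 120 synthetic images and evaluate on 30
mk <- function(n, base) {
  im <- array(0, c(64, 64, 3, n)); ms <- array(0, c(64, 64, 1, n))
  for (i in 1:n) {
    s <- dermseg:::sampleScene(64, 64, hair = hairSpec(), seed = base + i)
    im[,,,i] <- s$image / 255; ms[,,1,i] <- s$mask
  }
  list(images = im, masks = ms)
}
tr <- mk(120, 1000); va <- mk(30, 2000)
cfg <- ModelConfig(encoderFilters = c(8L, 16L), bottleneckFilters = 32L,
                   inputSize = 64L)
fit <- trainModel(buildModel(cfg, seed = 1), tr$images, tr$masks,
                  va$images, va$masks,
                  TrainConfig(batchSize = 8L, maxEpochs = 15L, seed = 1L))
evaluateModel(fit$model, va$images, va$masks)
#> MetricsReport (per-image-mean (dice, iou) + pooled (pa, precision, recall, auc), 30 images)
#>   dice            0.8628
#>   iou             0.7607
#>   pixel_accuracy  0.9611
#>   precision       0.8003
#>   recall          0.9438
#>   auc             0.9831
```

The report's Dice/Jaccard are per-image means (every lesion counts
equally regardless of size); accuracy, precision, recall and AUC are
pooled over all validation pixels. A Dice around 0.85 on this miniature
problem says the architecture trains and segments scenes with the
assumed structure — claims about real dermoscopy require real data.

A thin command-line wrapper is installed with the package
(`inst/scripts/dermseg`) exposing `simulate`, `preprocess`, `train`,
`evaluate`, `predict` and `ablate` subcommands over the same
functions.

## Vignette

`vignettes/lesion-segmentation.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and the
package's numerical conventions and limitations.
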