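---
title: "Methods: lightweight pyramid-attention networks for leaf maturity"
author: "leafnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lightweight pyramid-attention networks for leaf maturity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Harvest decisions for broadleaf crops such as tobacco hinge on leaf
maturity, judged in the field from colour and texture. `leafnet` implements
a nine-class image classifier for this task — stalk position (lower,
middle, upper) crossed with ripeness stage (under-mature, mature,
over-mature) — designed to be light enough for phone-class hardware, plus
the full experimental harness around it: data pipeline, training protocol,
metric suite, perturbation-robustness grid and gradient-free
explainability.

The field imagery such models are trained on is typically private. The
package therefore ships a synthetic leaf-image generator that reproduces
the *structure* of such a dataset (nine classes, realistic per-class
imbalance, cluttered backgrounds) so that every part of the stack is
testable end to end without any download.

## Model

The backbone is the standard thirteen-stage depthwise-separable
architecture: a 3x3 stride-2 stem followed by thirteen blocks of
(3x3 depthwise convolution, BatchNorm, ReLU, 1x1 pointwise convolution,
BatchNorm, ReLU), with channel widths 32, 64, 128, 128, 256, 256, 512,
512, 512, 512, 512, 512, 1024, 1024 and stride-2 depthwise convolutions in
blocks 2, 4, 6 and 12. A width multiplier scales every backbone width.

Five taps C1..C5 are taken after the pointwise ReLUs of stages 1, 3, 5, 11
and 13 (spatial sizes 112, 56, 28, 14, 7 at 224x224 input; widths 64, 128,
256, 512, 1024). A feature pyramid projects each tap with a biased 1x1
convolution to 64 channels and fuses top-down:

    P5 = lateral(C5)
    Pi = lateral(Ci) + up2(P(i+1)),   i = 4..1

where `up2` is parameter-free bilinear 2x upsampling (half-pixel
convention) and fusion is elementwise addition. Spatial attention (SP) acts
on P2 *before* its fusion into P1: the channel mean and max maps are
concatenated and passed through one biased 3x3 convolution and a sigmoid,
giving a per-location gate. Squeeze-and-excitation (SE) acts on the fused
P1: global average pooling to a 64-vector, a bias-free bottleneck pair of
dense maps (64 -> 2 -> 64, ratio 32) with ReLU and sigmoid, and channelwise
rescaling. The head is BatchNorm, global average pooling and a dense
softmax layer over the nine classes. The plain backbone classifier omits
the pyramid entirely (GAP and a dense layer on C5).

Several architectural details are not fully determined by prose
descriptions of such models; the package pins them by exact parameter
accounting. With biased laterals, parameter-free fusion and upsampling, a
19-parameter SP block (3x3x2 kernel + bias), a 256-parameter bias-free SE
bottleneck, and a head BatchNorm on 64 channels, the enhanced classifier
totals exactly 3,357,276 parameters and the plain baseline 3,238,089
(BatchNorm moving statistics included, as frameworks count them). These
two integers are the package's structural reference values; any deviation
in lateral bias handling, SE biasing, fusion operator or head wiring
breaks them, which is what `tests/` and `scripts/acceptance.R` assert.
The head consumes only the SE-recalibrated P1; the coarser levels
influence it through top-down fusion. Dropout is absent everywhere — any
dropout layer would leave the totals unchanged only if empty, and the
simplest reading consistent with both totals has none.

```{r}
library(leafnet)
full <- build_variant(model_config())
count_parameters(full)    # 3357276
```

## Numerical engine

No deep-learning framework is assumed: forward and backward passes are
implemented in the package itself, with Rcpp kernels for the
memory-intensive primitives (im2col, depthwise convolution, bilinear
resampling, fused BatchNorm+ReLU) and BLAS matrix products for the
pointwise convolutions and dense layers. Activations are stored as
`(H*W*N) x C` matrices in column-major (height, width, image) order.
Correctness of the hand-derived backward pass is enforced by
finite-difference tests: a directional derivative over *all* trainable
parameters must match the analytic gradient to 0.1% (0.5% for the plain
backbone; the loss surface is only piecewise smooth, so per-coordinate
checks use the smooth head parameters).

Numerical choices, all asserted in tests where they are observable:

* BatchNorm: eps 1e-3; training mode uses biased batch moments; moving
  statistics decay with momentum 0.8, chosen so inference statistics burn
  in within a few dozen optimizer steps — at the short training budgets
  this package targets, slower decays leave the inference path badly
  miscalibrated for several epochs.
* "Same" padding: symmetric for stride-1 convolutions, top-left-biased
  (0 top, 1 bottom) for stride-2, so even sizes halve exactly and the tap
  geometry follows the 112/56/28/14/7 schedule.
* Bilinear resampling uses the half-pixel (align-corners-off) convention
  everywhere: image resizing, pyramid upsampling, heatmap rendering.
* Weight init: He-normal scaled by fan-in; BatchNorm gamma 1, beta 0.
* Softmax rows are max-shifted; cross-entropy clamps probabilities at
  1e-12.
* OpenBLAS is pinned to one thread at load: the network's GEMMs are small
  and memory-bound, and thread fan-out costs more than it buys.

## Training protocol

Categorical cross-entropy, minibatches of 32, 30 epochs by default;
optimizers SGD, RMSprop and Adam (ecosystem-default hyperparameters:
Adam beta 0.9/0.999, RMSprop rho 0.9, eps 1e-7) at initial learning rates
5e-3, 5e-4 and 5e-5 form the supported grid, summarized by the
final-five-epoch mean of the validation metrics. The learning-rate
schedule is reduce-on-plateau: if the validation loss has not *strictly*
decreased for five consecutive epochs, the rate is halved and the counter
resets (ties count as non-improvement; minimal delta 0). There is no early
stopping and no weight decay. Pretrained initialization is deliberately
absent: it would require a download, and the synthetic tasks are learnable
from random init.

The data pipeline splits 7:2:1 stratified within class, allocating
`round(0.7 n)` and `round(0.2 n)` items per class under round-half-to-even
(this rounding rule is load-bearing: applied to the nine field per-class
counts — 215, 298, 200, 248, 279, 194, 251, 255, 219, which sum to 2,159 —
it yields exactly 1,511 training images, where floor would give 1,507 and
half-up 1,513). Offline augmentation expands each training image into six:
the original, 90 and 270 degree rotations, a horizontal mirror, a
brightness rescale by u ~ U(0.8, 1.2) and Gaussian pixel noise with sd
0.02; 1,511 * 6 = 9,066. Right-angle rotations were chosen over arbitrary
angles for determinism and label safety. Augmentation randomness derives
from a per-item seed hashed from the global seed and the item id, so the
expansion is reproducible item by item and never touches validation or
test data.

## The synthetic generator

`generate_leaf_image()` draws an elliptical leaf with a dark midrib and
oblique lateral veins over a brownish soil background with weed-like green
blobs. Ripeness controls the lamina colour along a green (under) ->
yellow-green (mature) -> yellow-brown (over) axis, with dark necrotic
spots added on over-mature leaves; stalk position controls leaf size and
aspect (lower leaves large and broad, upper small and slender). Everything
is deterministic given (class, seed, size). Default per-class counts are
the nine field counts above; their printed sum is 2,159 even though the
source text states 2,160 — the per-class figures are taken as
authoritative. `clutter_level` scales the number of weed blobs (default
0.2, at which a linear discriminant on mean RGB separates the three
ripeness stages with over 80% accuracy — the floor that guarantees
smoke-training is feasible at all).

What the generator does *not* model: camera optics, specular highlights,
leaf occlusion by other leaves, weather variation, or continuous maturity
gradients. Passing tests on synthetic data therefore demonstrate that the
architecture, optimization and evaluation machinery are correct — not that
the trained weights would transfer to field imagery.

## Problem sizes in the test suite

The suite runs every component at deliberately small scale: unit tests use
32x32 inputs with a quarter-width backbone; the end-to-end smoke check
trains the full pyramid-attention variant at 96x96, width 0.25, on 50
images per class of clutter-free synthetic data (the easiest regime the
generator produces) for 10 epochs with Adam at learning rate 5e-3 and minibatches of 8, and
requires a median final validation accuracy of at least 0.90 over three
seeds. The short budget dictates these choices: 5e-3 is the top of the
supported learning-rate grid, and the smaller batch quadruples the number
of optimizer steps an epoch provides; at the grid's long-run winner
(5e-4, batch 32) the model is still far from converged after ten epochs. The ablation check trains all five
variants for one epoch each on the same data and reports the five-row
table with exact parameter counts.

## Robustness and explanation

The robustness harness perturbs a class-stratified random subset
(proportion 0.3, 0.7 or 1.0) of the evaluation set and reports per-class
accuracy per condition. Noise intensities are standard deviations in
normalized [0,1] pixel units (0.1, 0.5); brightness is scalar
multiplication (0.8, 1.2) with clipping; occlusion blacks out one square
patch of side `round(sqrt(ratio * H * W))` placed uniformly inside the
image — the simplest faithful reading of an "occlusion ratio". All
perturbations are applied after resizing to the model input.

Score-CAM explains a prediction without gradients: each channel of a
chosen activation layer is upsampled, min-max normalized (a constant
channel becomes an all-zero mask, guarding against division by zero),
used to mask the input, and scored by a forward pass; the softmax over
these target-class scores weights the channels, and the CAM is the ReLU of
the weighted sum, upsampled and normalized. The channel weighting uses raw
masked-input scores (no baseline subtraction). Results are invariant to
the masking batch size, which is asserted in tests, and the vectorized
implementation is checked against a naive channel-at-a-time loop to 1e-5.
The default layer for both Score-CAM and the max-activation overlay is the
final pre-head feature map (the SE output in the full variant), the layer
closest to the decision that still has spatial extent.

## Known limitations

* Weight determinism across BLAS builds is best-effort: data order and
  every stochastic choice are seed-stable, but floating-point accumulation
  order inside BLAS may differ between platforms.
* The engine is CPU-only and tuned for small inputs; it is an auditable
  reference implementation, not a speed-competitive trainer at 224x224
  scale.
* The "mPA" column of published comparison tables could not be tied to a
  defined estimator (it equals test accuracy for most models yet not for
  all) and is deliberately not computed.
* FPS measurements are wall-clock and hardware-dependent; they are
  reported for information and never asserted against reference values.
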