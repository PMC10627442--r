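---
title: "Dual-branch U-Net segmentation: models, losses, and validation design"
author: "dbunet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch U-Net segmentation: models, losses, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbunet)
```

## The problem and the model

Breast ultrasound images are low-contrast, speckle-textured, and lesion
boundaries are fuzzy; segmenting the hypoechoic (darker) tumor region is the
step everything downstream depends on. `dbunet` implements a dual-branch
encoder U-Net (DBU-Net) for this task. One encoder branch consumes the raw
grayscale image; the other consumes a binary Roberts-cross edge map of the
same image, in which intensity discontinuities — typically dense around a
lesion margin — are made explicit. The two branches exchange information
after every encoder level through a learnable weighted cross-fusion

$$F_x' = F_x + (W_x F_x + W_y F_y), \qquad
  F_y' = F_y + (W_x F_x + W_y F_y),$$

where $F_x$, $F_y$ are the pooled feature maps of the image and edge branch,
and $W_x$, $W_y$ are scalar weights, one pair per encoder level, initialized
at exactly 1 and updated by the optimizer jointly with all other parameters.
Both updates use the *pre-update* maps, and the residual term preserves each
branch's identity, so the branches cannot collapse into one another. With
all fusion weights at zero the primary path reduces exactly to the
single-branch baseline (GSU-Net), which the test suite verifies numerically.

### Architecture

Each encoder level applies two 3x3 convolutions (same padding, ReLU), a 2x2
max-pool with stride 2, and dropout (probability 0.2). The decoder mirrors
this: bilinear 2x upsampling, a 2x2 convolution halving the channels,
concatenation with the skip feature map, then two 3x3 convolution + ReLU
layers; a final 1x1 convolution and sigmoid produce the probability map.
Channel widths double per level (default 64 at the first level, depth 4,
bottleneck 1024; the widths are a design choice — classic U-Net — as is
everything the architecture description leaves open).

Three placement decisions were genuinely open and are resolved as follows:

* **Fusion position.** Fusion operates on the *pooled, dropped-out* maps of
  each level (convolutions, pooling, dropout, then fusion), matching the
  order in which the operations are described.
* **Skip connections.** Fused maps exist only at the pooled resolution, so
  they cannot serve as same-resolution skips. Skips therefore carry the
  *primary branch's* conv-block outputs (pre-pool, full resolution); the
  fused maps feed the next encoder level and the bottleneck. This is the
  minimal reading that keeps the GSU-Net equivalence limit exact.
* **Symmetry.** The cross-fusion update is often stated for the primary
  branch alone; we apply it symmetrically to both branches with the shared
  weighted sum, because crosswise exchange only works if the edge branch
  also remains informative at the next level. One $(W_x, W_y)$ pair per
  level, shared by both branch updates, is the smallest parameterization
  that still weights each feature type separately.

### The Roberts edge pipeline

The Roberts cross kernels are $\delta_x = \begin{pmatrix}1&0\\0&-1
\end{pmatrix}$, $\delta_y = \begin{pmatrix}0&1\\-1&0\end{pmatrix}$, applied
as valid cross-correlation anchored at the top-left. The gradient magnitude
is $G = \sqrt{G_x^2 + G_y^2}$; the binarization threshold is the arithmetic
mean of $G$ over all entries, and a pixel is an edge pixel iff its magnitude
*strictly* exceeds the threshold (ties go to background, so a constant image
yields an empty edge map). To keep the edge map the same size as the network
input we replicate-pad the image before the valid correlation rather than
rescaling afterwards; for the 2x2 Roberts kernels the padding is one
replicated row/column at the bottom/right (matching the top-left anchor),
for the 3x3 Prewitt ($[-1, 0, 1]$ columns) and Sobel ($[-1, 0, 1]$ with
center row doubled) variants it is symmetric. The Prewitt/Sobel pairs
satisfy the transpose relation $O_x^\top = O_y$; the Roberts pair is instead
related by a 90-degree rotation ($\delta_x^\top = \delta_x$,
$\delta_y^\top = -\delta_y$), and the tests assert exactly these symmetries.

### Loss

Training minimizes a hybrid of the alpha-balanced focal loss and the soft
dice loss:

$$\mathcal{L} = \underbrace{-\,\overline{\alpha_t (1 - P_t)^\gamma \ln
P_t}}_{\text{focal}} \; + \; \underbrace{1 - \frac{2\sum p\,t +
s}{\sum p + \sum t + s}}_{\text{dice}},$$

with $\gamma = 2$, $\alpha = 0.25$ on the positive class ($1 - \alpha$ on
the background, the standard alpha-balanced form), natural logarithm, and
smoothing constant $s = 1$. Probabilities are clipped to
$[10^{-7}, 1 - 10^{-7}]$ before the logarithm. The focal part is averaged
over pixels and then over the batch; the dice part is computed per image
(soft, on probabilities) and averaged over the batch. Reported metrics use
hard masks at threshold 0.5: pixel accuracy, IoU and DSC, computed per image
and averaged over the test fold, with the empty-vs-empty convention
IoU = DSC = 1. With $\gamma = 0$, $\alpha = 0.5$ the focal term is exactly
half the binary cross-entropy, which the tests use as an oracle.

### Training protocol

`trainFold()` follows the tuned settings: Adam, batch 16, at most 50
epochs, initial learning rate $10^{-4}$, reduce-on-plateau (after 3
consecutive epochs without a validation-loss improvement of at least
`minDelta` = 1e-4, multiply the rate by 0.2), and early stopping. Two
choices were open:

* Five-fold protocols often monitor convergence on the test fold itself; to
  avoid that leakage we hold out 10% of each training fold for the
  plateau/early-stop monitor and never touch the test fold during training.
* Early stopping patience is unstated; we use 8 non-improving epochs with
  restoration of the best-validation weights.

`plateauSchedule()` exposes the decay rule as a pure function of a
validation-loss trace; on a trace with one improving epoch followed by seven
flat ones it yields the rate sequence 1e-4, 2e-5, 4e-6.

## Numerical implementation

No deep-learning framework is available to R here, and none is needed at
this scale: the forward and backward passes are implemented directly.
Feature maps are `(H, W, batch, channel)` arrays; each convolution is an
im2col gather (compiled, `src/conv_ops.cpp`) followed by a single BLAS
matrix product, and the backward pass is the corresponding transposed
product plus a col2im scatter-add. Max-pool ties route the gradient to the
first maximal corner (fixed scan order); dropout uses inverted scaling so
evaluation needs no correction; bilinear resampling is a separable linear
map with half-pixel centers and clamped borders (rows sum to 1, so constant
maps are preserved, and its transpose is the exact backward operator).
Weights are Glorot-uniform initialized under a pinned seed; every stochastic
element (initialization, batch order, dropout masks) is controlled by one
seed, and two runs with the same seed are bit-identical. The analytic
gradients are verified against central finite differences in the test suite
(away from ReLU kinks, where the loss is differentiable).

## The synthetic phantom generator

Real breast-ultrasound data cannot ship with a package, so every experiment
runs on synthetic phantoms built to exhibit exactly the properties the
method exploits: (i) multiplicative speckle, modeled as Gaussian-smoothed
exponential noise scaled to unit mean — a standard surrogate for coherent
interference; (ii) a hypoechoic lesion, an ellipse whose intensity is
multiplied by $1 - \texttt{intensityDrop}$; (iii) a fuzzy, irregular
boundary, produced by radially jittering the ellipse with three random
Fourier harmonics and Gaussian-blurring the intensity step. The ground-truth
mask is the un-blurred lesion support. Classes ("benign"/"malignant", drawn
roughly 2:1) differ only in jitter amplitude and exist to exercise
stratified folding; with probability `multiMaskProb` the mask is emitted as
two overlapping components whose union is the truth, exercising the
mask-merging rule. Generation is deterministic in `(seed, index)`.

What the phantoms do *not* emulate: acoustic shadowing, depth-dependent
attenuation, anatomical texture, multiple or non-elliptical lesions, and
realistic speckle correlation. Passing the phantom experiments therefore
demonstrates that the implementation learns and generalizes, not that it
reaches clinical-grade accuracy on real ultrasound.

## Desk-scale experiment sizes

The validation experiments are sized for a single CPU: phantoms are 64x64,
the tiny network preset has depth 2 and 8 base channels, training uses Adam
at 1e-3 with batch 8 (a standard small-scale rate; the 1e-4 production rate
pairs with batch 16 and 50-epoch schedules). The overfit check fits 8
phantoms for at most 300 steps; the generalization check trains on 64
phantoms for 120 steps and evaluates 16 held-out phantoms, for three seeds
and both architectures. Stratified 5-fold splitting, fold training and
cross-validation are exercised at the same scale.

## Known limitations

* On these phantoms both architectures converge to held-out DSC around
  0.92 — near the ceiling set by the blurred boundary — and the dual-branch
  model's advantage over the single-branch baseline is not resolvable:
  across the three seeds of the comparison experiment the mean difference is
  a fraction of a DSC point and changes sign between seeds. The lesion here
  is separable from intensity alone, so the edge branch adds capacity but
  little information; the architecture's motivating regime (boundaries that
  are the hard part) is precisely what a simple phantom cannot reproduce.
  The acceptance experiment reports both numbers honestly rather than
  tuning the generator until the expected ordering appears.
* The exact Wilcoxon test enumerates all $2^n$ sign assignments and is
  limited to $n \le 20$; there is deliberately no normal-approximation
  fallback. With 5 folds the smallest attainable one-sided p-value is
  $1/32 = 0.03125$.
* `aggregateFolds()` uses the sample (n-1) standard deviation throughout.
  Published fold tables are not always consistent about the divisor; the
  acceptance tests document one benchmark table whose printed values follow
  the population (n) convention instead.
* Images are preprocessed to a fixed square size by bilinear interpolation
  regardless of aspect ratio, masks by nearest-neighbor (so they stay
  binary); masks are merged before resizing so component boundaries cannot
  acquire interpolation seams.
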