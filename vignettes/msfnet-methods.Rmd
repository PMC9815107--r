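---
title: "Multi-scale fusion attention networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale fusion attention networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfnet)
```

## The problem and the model

msfnet classifies leaf photographs into disease categories (the motivating
system is cassava: bacterial blight, brown streak disease, green mottle,
mosaic disease, and healthy leaves). Disease evidence lives at several
spatial scales at once — lesion colour and texture are fine, high-resolution
cues, while lesion extent and leaf deformation are coarse ones — and the
classes are naturally imbalanced in field collections. The package addresses
both with a single architectural idea and a matching loss:

1. a **multi-scale fusion module (MSFM)** that recalibrates shallow,
   high-resolution features with convolutional block attention and then reads
   them at three receptive-field sizes simultaneously through dilated
   convolutions, and
2. **focal loss**, which keeps abundant easy classes from dominating the
   gradient signal.

### Convolutional block attention (CBAM)

For a feature map $F \in \mathbb{R}^{C \times H \times W}$, channel attention
pools $F$ globally by max and by average, passes both length-$C$ descriptors
through one *shared* two-layer ReLU MLP with bottleneck width
$\max(1, \lfloor C/r \rfloor)$, sums the two outputs and squashes with a
sigmoid:

$$ s = \sigma\!\big(\mathrm{MLP}(\mathrm{maxpool}(F)) +
\mathrm{MLP}(\mathrm{avgpool}(F))\big) \in (0,1)^C . $$

Spatial attention then takes the channel-wise max and mean of the gated map
$F' = F \odot s$, concatenates them to a $2 \times H \times W$ stack, reduces
to one channel with a single $k \times k$ convolution and squashes again:

$$ M = \sigma\!\big(\mathrm{conv}_{k\times k}([\max_c F';\ \mathrm{mean}_c
F'])\big) \in (0,1)^{H \times W}, \qquad F'' = F' \odot M . $$

Both gates are multiplicative and sigmoid-bounded, so CBAM never amplifies:
$|F''| \le |F|$ elementwise. Channel attention is applied first, spatial
second; the MLP has no biases.

### Dilated convolutions and the fusion module

A $k \times k$ kernel with dilation rate $r$ spaces its taps $r$ pixels
apart. Its tap bounding box has side

$$ k_d = k + (k-1)(r-1), $$

so a $3\times3$ kernel at rate 2 covers a $5\times5$ region with only 9
trainable weights instead of 25. The MSFM applies CBAM, then three parallel
$3\times3$ branches at rates 1, 2 and 4 (each zero-padded by $r$, so all
branch outputs keep the input's spatial extent), concatenates the branch
outputs along channels and reduces with a $1\times1$ convolution. A
`fusion = "sum"` variant replaces concatenation with an elementwise sum; the
default is concatenation, which preserves each scale's information until the
learned reduction.

### Backbone and assembly

The classifier is an EfficientNet-B6-*shaped* backbone: the B6 stage table
(widths 32/40/72/144/200/344/576, depths 3/6/6/8/9/11/3, strides
1/2/2/2/1/2/1, stem width 56, head width 2304) with each block realised as a
3×3 convolution → batch normalization → swish. The package deliberately does
not reproduce MBConv internals (inverted bottlenecks, depthwise kernels,
squeeze-excitation): the experimental surface here is the fusion module, the
attention gating and the loss, and a plain conv-BN-swish realisation of the
same stage geometry keeps every one of those components exactly testable
(each layer carries a hand-derived backward pass that the test suite checks
against numeric differentiation). The MSFM replaces the feature stream after
stage 2 — shallow, high-resolution features — and every later stage ends
with a CBAM gate placed immediately before that stage's final normalization.
Both choices are configurable (`msfm_stage`, `cbam_stages`); replacement
(not summation) of the stream is the fixed behaviour.

`width_multiplier` and `depth_multiplier` shrink the stage table for
test-scale models, mirroring the two axes of compound scaling. Widths round
to multiples of 4 with a floor of 4; depths use a ceiling with a floor of 1.

### Focal loss

With $p_t$ the predicted probability of the true class,

$$ \mathrm{FL}(p_t) = -\alpha_t (1-p_t)^{\gamma} \log p_t , $$

which equals the weighted cross-entropy $-\alpha_t \log p_t$ exactly at
$\gamma = 0$ and is bounded above by it for $\gamma > 0$. The default is
$\gamma = 2$; $\alpha$ defaults to inverse-frequency weights
$N/(K\,n_c)$ computed on the training split only. $p_t$ is clamped to
$[10^{-7}, 1]$ before the logarithm so the loss is never NaN; a warning
accompanies any clamp. The multiclass batch loss sums the true-class terms,
and `mean` reduction divides by the batch size.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| channel-MLP reduction `r` | 16 | squeeze-excitation convention; hidden width floors at 1 so no divisibility constraint |
| spatial kernel | 7 | the usual CBAM choice; must be odd for "same" padding |
| dilation rates | 1, 2, 4 | three octaves of receptive field from the same 9-weight kernel |
| branch / output width | input width | makes the module drop-in shape-preserving |
| input resolution | 224 px | the standard classifier input size; configurable |
| epochs / lr / batch | 150 / 1e-4 / 16 | the reference training protocol; Adam ($\beta$ 0.9/0.999) with no schedule, since only an initial rate is specified |
| $\gamma$ / $\alpha$ | 2 / inverse frequency | both are mandatory, logged config entries — the focal-loss literature default and the standard imbalance correction |
| split ratios | 8:1:1 | the training protocol; a 90/10 preset covers the plain train/test division |

## Numerical and design choices

- **Spatial-attention padding.** The reducing convolution pads by *edge
  replication*, not zeros. Under zero padding a spatially constant map would
  get a non-uniform gate at the borders; replicate padding makes "constant
  in, uniform out" exact, which is both the natural semantics of an
  attention gate and a property the test suite asserts. The dilated branches
  keep conventional zero padding of width $r$.
- **Brightness rounding.** The augmentation multiplies by the factor, rounds
  half away from zero, then clips to 0..255 — declared so results are
  bit-stable across platforms.
- **Offline augmentation.** The recipe (180° rotation, brightness × 0.7,
  horizontal flip) emits provenance-tagged records; variants can be
  materialized to disk or applied lazily on read. An optional brightness
  *increase* (default factor 1.3) exists but is off in the reference recipe.
  When a per-class cap is set, truncation follows a deterministic order
  (originals, rotations, brightness variants, flips). Splits are computed
  before augmentation in the command-line pipeline, so variants of one image
  never straddle train and test.
- **Split apportionment.** Largest-remainder apportionment, per class when
  stratified, ties resolved toward the earlier split. This makes 22,000
  records at 90/10 come out exactly 19,800/2,200 and 10 records at 8:1:1
  exactly 8/1/1.
- **Degenerate metric denominators** yield 0 with a `flagged` marker, never
  NaN. Confusion matrices are fixed as rows = truth, columns = prediction in
  every output.
- **Grad-CAM.** The explained layer defaults to the MSFM output; gradients
  are taken with the exact layer-by-layer backward pass, channel weights are
  global averages of the gradient, and the rectified weighted sum is
  bilinearly upsampled (half-pixel centres, edge clamping) and min-max
  normalized. A constant raw map normalizes to all zeros and sets a
  `constant` flag instead of dividing by zero.
- **Determinism.** All randomness flows through explicit seeds
  (initialization, shuffling, the synthetic generator); the RNG state of the
  caller is always restored. Two runs with the same seed and config are
  identical on one platform, which the suite verifies to 1e-6 on full
  training trajectories.

## The synthetic generator

`generate_synthetic_dataset()` renders the study conditions without external
data: a textured leaf-green background (low-frequency cosine fields plus
Gaussian pixel noise, sd 8) carrying class-specific motifs — pale angular
blotches, brown elongated streaks, green-on-green mottle dots, yellow mosaic
patches, or nothing for healthy leaves. Default geometry is 600 × 800 px,
the shape of the field photographs it emulates; motif counts, colours and
sizes are exposed in `class_spec` and scale with the image. Class imbalance
is configurable by passing one count per class.

The generator carries colour-statistics signal by construction (a trivial
per-channel-mean classifier already beats chance, which the suite checks),
so passing smoke-training tests demonstrates that the optimization loop,
attention blocks and loss work — it does *not* demonstrate field-image
accuracy. Real leaf photographs vary in pose, illumination, occlusion and
background clutter that the generator deliberately omits; claims about real
data require the real dataset.

## Problem sizes used by the test suite

Tests run the same code paths at reduced scale, chosen so the whole suite
stays fast while still exercising every module: width and depth multipliers
of 0.1, resolutions 32–64 px, synthetic folders of 2–50 images per class,
and 1–3 training epochs for contract checks. The smoke-training check uses
the seeded five-class set (50 images per class, 64 × 64) with focal loss at
learning rate 1e-3 — a rate appropriate for a ~58k-parameter model — and
requires ≥ 90% training accuracy within 30 epochs. Gradient correctness is
checked by central differences on small instances of every layer kind and
through the assembled network.

## Known limitations

- The backbone realises the B6 stage geometry, not MBConv internals; no
  pretrained weights are shipped or required.
- Training is single-CPU, full-precision, and intended for moderate image
  counts; there is no multi-device path.
- JPEG reading requires EBImage; the package's own outputs are PNG.
- Grad-CAM heatmaps are qualitative; no localization ground truth exists in
  the intended datasets, so no quantitative localization metric is offered.
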