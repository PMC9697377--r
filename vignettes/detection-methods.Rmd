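---
title: "Methods: deformable convolution, attention-weighted feature pyramids, and two-stage pest detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deformable convolution, attention pyramids, two-stage pest detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pestdetectr)
```

## The problem

Field images of crop pests are hard for detectors in three specific ways:
pest instances are often tiny relative to the frame (box areas below 1% of
the image are common), class frequencies are strongly imbalanced (a few
abundant species dominate the annotations), and instances occur occluded or
densely clustered. `pestdetectr` implements a two-stage convolutional
detector aimed at exactly these regimes, together with the complete
evaluation stack and a seeded synthetic scene generator, so that every part
of the pipeline can be exercised and audited on a single CPU without any
external dataset.

## The model

### Deformable convolution

A standard convolution reads the input at a fixed grid of taps. The
deformable variant displaces each tap by a learned, per-output-position
2-D offset:

$$y(l_0) = \sum_{l_n \in \Omega} w(l_n)\, x(l_0 + l_n + \Delta l_n)$$

where $\Omega$ is the 3×3 sampling grid, $w$ the kernel weights, and
$\Delta l_n$ the offsets. Offsets are produced by an ordinary 3×3,
dilation-1, stride-1 convolution of the same input, so the offset field has
the spatial size of the output. Because displaced positions are fractional,
values are read through the separable tent (bilinear) kernel

$$G(k, l) = \max(0, 1 - |k_x - l_x|)\cdot\max(0, 1 - |k_y - l_y|),$$

which also implies zero padding: positions more than one pixel outside the
grid contribute nothing. Gradients flow to the weights, the input, *and*
the offsets (the tent kernel is piecewise linear in $l$), which is what
makes the sampling geometry learnable; `test-autodiff.R` and
`test-deform-backbone.R` verify all three gradient paths against central
finite differences.

Two properties anchor the implementation:

* **Zero-offset equivalence.** With all offsets zero the operation *is* a
  standard convolution. Offset-predicting convolutions are therefore
  zero-initialized, so a freshly built deformable network computes exactly
  the same function as its regular twin — a strong initialization (training
  starts from a known-good operator) and a sharp test oracle.
* **One offset pair per tap, shared across input channels**, matching the
  formulation above; no per-tap modulation scalar (that belongs to a
  different method family and is out of scope).

The backbone is a residual network. Three depth variants are provided
(`tiny`, `resnet18`, `resnet50`); stages C2–C5 emit features at strides
4, 8, 16, 32. Which stages are deformable is configurable; the default is
C3–C5, the common choice for deformable residual networks. The `tiny`
variant (stem 8 channels; stage widths 8/16/24/32; one basic block per
stage) exists because this package trains on a CPU: it is the variant all
tests and examples use.

### Attention-weighted feature fusion (the pyramid neck)

A feature pyramid network (FPN) fuses adjacent scales as

$$P_i = B_i(X_i) + \alpha\, F_{up}(P_{i+1})$$

with $B_i$ a 1×1 channel projection, $F_{up}$ nearest-neighbour 2×
upsampling, and the fusion factor $\alpha$ fixed at 1. Here $\alpha$ is
instead *generated from the upsampled upper pathway* by a small network —
sigmoid(conv3×3(relu(conv1×1(·)))) — giving each fused level its own
weight map in (0, 1). Each fused level then passes a 3×3 smoothing
convolution (removing nearest-upsampling aliasing), and the fifth level P6
is a stride-2 max subsampling of P5. The attention maps used are recorded
in the output for inspection.

Decisions taken where the design was genuinely open:

* **Map, not scalar.** The weight generator produces a single-channel
  spatial map broadcast across channels ("weight maps" suggests spatial
  structure; it also subsumes the scalar case). A per-channel variant sits
  behind `attention_channels = d`.
* **Generator hidden width** defaults to d/4 between the 1×1 and 3×3
  convolutions.
* **Pyramid inputs.** The two readings of "the top features P5 and P6 are
  obtained by twice subsampling" are both available: the default takes
  laterals from C2–C5 with P6 subsampled from P5 (the standard FPN
  layout); `literal_subsample_variant = TRUE` takes laterals from C2–C4
  and subsamples both P5 and P6.
* **Exact-FPN bypass.** A sigmoid never reaches 1, so plain-FPN behaviour
  is unreachable by the generator itself. `build_pyramid(..., bypass =
  TRUE)` forces $\alpha \equiv 1$; the equivalence test reduces the whole
  neck to an independently composed plain FPN to below 1e-5 max-abs
  difference.
* Pyramid width d defaults to 256 (the FPN convention) in the `full`
  preset and 32 in the `tiny` preset.

### Two-stage assembly

A region proposal network (3×3 conv + two 1×1 heads, shared across levels)
scores one anchor scale with aspect ratios 0.5/1/2 at every position of
every pyramid level. Decoded proposals are clipped, filtered by objectness
NMS (threshold 0.7), and pooled with ROI-align (bilinear sampling on a
fixed bin grid, so gradients reach the pyramid). Pooled features pass two
fully connected layers into a classification layer with $c+1$ outputs
(softmax over the $c$ pest classes plus background) and a localization
layer with $4c$ outputs — class-specific box deltas in the standard
$(dx, dy, dw, dh)$ log-space parameterization.

Training follows the conventional two-stage recipe with all knobs surfaced
in `detector_config()`: anchor IoU thresholds 0.7/0.3, balanced objectness
batches (64 anchors, ≤50% positive), ROI batches of 32 with ≤25% positives
at IoU ≥ 0.5, ground-truth boxes appended to the training ROIs, binary
cross-entropy + smooth-L1 for the RPN and softmax cross-entropy +
smooth-L1 for the heads, all loss weights 1. Optimization is SGD with
momentum 0.9, weight decay 1e-4, global gradient-norm clipping at 10, and
a 50-step linear warmup. One integer seed drives parameter initialization,
data order, and target sampling; there are no nondeterministic kernels, so
runs are exactly reproducible and checkpoints resume bit-identically (the
test suite asserts both).

No normalization layers are used: batches are single images, ruling out
batch statistics, and at the scales trained here plain He initialization
with warmup is stable. This is a deliberate simplification; it is the main
reason the `full` preset should be considered a structural reference
rather than a tuned large-scale trainer.

## Evaluation stack

Boxes are center-form $(x, y, w, h, \kappa)$ tuples, converted to
half-open continuous corner rectangles for all area arithmetic (no ±1-pixel
ambiguity). The accuracy metrics follow the standard definitions: IoU
$= \mathrm{area}(G \cap P)/\mathrm{area}(G \cup P)$; a detection is a true
positive iff its IoU with an unconsumed same-image ground-truth box
*strictly exceeds* 0.5 (the strict reading of "greater than 0.5"; many
toolkits use ≥ — both are available, strict is the default); matching is
greedy in descending confidence with ties broken by input order, each
ground truth consumed at most once. Precision/recall points accumulate
over the ranked detections; AP integrates the monotone-envelope
precision–recall curve with all-point interpolation (the literal "area
under the curve"; the 11-point variant is selectable); mAP is the
arithmetic per-class mean. Per-class recall in reports is the final point
of the sweep (confidence threshold → 0), matching how detection tables
pair Recall with AP. Classes without ground truth report 0 with a warning
rather than an undefined recall.

Every metric has an independent oracle in the test suite: loop-based
cumulative counting for precision/recall, and fine-grid Riemann
integration (20,000–100,000 recall points) of the envelope for AP, run on
a thousand random fixtures.

## The synthetic scene generator

The generator emulates the *statistics* that make pest datasets hard, not
their appearance: per-class relative box area sampled log-uniformly within
a configured range, mixture weights allowing strong imbalance, a
configurable instance count per image, an occlusion probability with an
IoU ceiling, and a textured background. Objects are rotated ellipses with
class-keyed colour and shading; each shape is scaled so its *bounding box*
area hits the sampled relative size, and the annotated box is re-measured
from the rasterized mask (the alpha = 0.5 contour sits exactly on the
nominal ellipse, so boxes are unbiased to ±1 px). One dataset seed is
stream-split into per-image seeds, so any single scene can be regenerated
independently and a whole dataset is bitwise reproducible.

Presets: `easy` (64×64, two high-contrast classes, box areas 6–20% of the
image, 1–2 instances, no occlusion) for scaled-down training;
`imbalanced-table1` (ten classes whose mixture weights follow instance
counts 55…7976 and whose size ranges bracket average relative sizes
0.007…0.306, the structure of a field corn-pest collection); `dense-small`
(8–15 instances of 0.2–1% area); `occluded` (overlap up to IoU 0.6 with
probability 0.8).

What passing tests on these scenes does **not** show: robustness to real
backgrounds, real pest morphology, illumination, or label noise. The
generator is a statistical testbed; claims about real-world accuracy are
out of scope by design.

## Problem sizes and numerical choices

The scaled-down end-to-end experiment — the package's own choice of
conditions — is: 200 easy scenes split 9:1 (floor rule:
$n_{train} = \lfloor 0.9N \rfloor$), the `tiny` preset, 5 epochs, learning
rate 0.02, evaluated as held-out mAP at IoU 0.5 with the verdict taken as
the median over three seeds. On these conditions training takes about a
minute per seed on one CPU and reaches mAP well above 50%.

Other numerical choices: anchors live at pixel centres ((i+0.5)·stride);
decoded $dw, dh$ are clamped at ±4 before exponentiation; degenerate
proposals narrower than 1 px are dropped; NMS breaks score ties by input
order; an empty PR curve yields AP 0 with a warning; image tensors are
(H, W, C) arrays in [0, 1] with 0.5 subtracted at the network input.

## Known limitations

* CPU-scale only; no pretrained weights; the `full` preset is structural.
* No modulated (v2-style) deformable convolution and no deformable ROI
  pooling; single-image batches; no normalization layers.
* COCO-style mAP@[.5:.95], confidence-threshold selection, and bootstrap
  intervals are intentionally absent.
* The synthetic scenes do not attempt photorealism; conclusions about real
  imagery require real annotations (the VOC reader accepts any
  LabelImg-produced dataset).
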