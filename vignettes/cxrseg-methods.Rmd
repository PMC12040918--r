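---
title: "Edge-enhanced U-Net segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-enhanced U-Net segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxrseg)
```

## The problem

Chest radiographs contain several anatomical structures a reader routinely
delineates — the lung fields, the cardiac silhouette, and the clavicles —
whose automated segmentation supports cardiothoracic assessment. Three
properties make this hard: intensity overlap between neighboring structures,
heavy class imbalance (lungs occupy an order of magnitude more pixels than
clavicles), and low boundary contrast, especially for the clavicles where
thin bars of bone cross the bright lung fields.

`cxrseg` implements a segmentation pipeline built around one idea: sharpen
the boundary information *before* the network sees the image. A gradient
operator (Sobel or Scharr) computes an edge-strength map that is blended
into the input, and a U-Net trained with a class-weighted focal loss does
the dense prediction.

## Edge operators

The horizontal and vertical gradients at pixel $(i,j)$ are the correlation
sums

$$g_x(i,j) = \sum_{u=-1}^{1}\sum_{v=-1}^{1} I(i+u, j+v)\, k_x(u{+}2, v{+}2),
\qquad
g(i,j) = \sqrt{g_x^2 + g_y^2},$$

with $k_x, k_y$ either the standard Sobel pair (weights $\pm 1, \pm 2$) or
the Scharr pair with $\pm 3, \pm 10$ weights, which has better rotational
symmetry. `convolve3x3()` evaluates the sums literally as correlation —
no kernel flip — because that is the index form of the defining equations;
the unit-impulse response is therefore the kernel rotated 180°, which the
tests assert. Three border rules are supported (`replicate`, mirror-style
`reflect`, `zero`); `replicate` is the default because it introduces no
spurious frame edges into medical images.

`enhance_image()` composes the network input:

1. optional CLAHE (local contrast normalization),
2. gradient magnitude by the chosen operator,
3. per-image min–max normalization of the magnitude to $[0,1]$,
4. optional adaptive mean thresholding of the magnitude, and
5. a convex blend `(1 − w)·image + w·edge`.

Whether the network should receive the pure edge map, a blend, or a stacked
two-channel input is genuinely open; this package blends (default
`blend_weight = 0.5`) because it preserves both readings — `w = 1` recovers
the pure-edge variant and `w = 0` the raw image — and leaves the choice as
one continuous, auditable parameter.

CLAHE is implemented in-package: 256-bin tile histograms are clipped at
`clip` times the uniform bin level, the excess is redistributed uniformly,
and per-pixel output bilinearly blends the four surrounding tile mappings.
With one tile and a non-binding clip this reduces *exactly* to global
histogram equalization, which the tests exploit as an independent oracle.
Clip limit, tile count, and the adaptive-threshold block/offset have no
canonical values for this task; the defaults (`clip = 2`, `tiles = 8`,
`block = 11`, `offset = 0.02`) are configuration, not findings.

## The network

`build_unet()` constructs a symmetric encoder–decoder with skip
connections: each encoder level applies two 3×3 same-padding convolutions
with ReLU and a 2×2 max pool, filter counts doubling per level; the decoder
mirrors this with nearest-neighbor upsampling and skip concatenation; a
final 1×1 projection feeds an elementwise **sigmoid**. The sigmoid (rather
than softmax) output is deliberate: anatomical classes can overlap
(clavicles cross lungs), so each channel is an independent probability and
prediction is multi-label. Binarization uses strict `p > threshold` with
default 0.5.

The implementation is plain R: convolutions are im2col gathers followed by
BLAS matrix products, and every backward pass is an exact analytic
gradient, verified against central finite differences in the test suite.
At the package's working scales (images up to a few hundred pixels per
side, depth 2–3) this trains in seconds to minutes on one CPU core.

## Loss, weights, schedule

Class imbalance is handled twice. First, inverse-frequency class weights:
$f_c$ is the fraction of all mask pixels belonging to class $c$, the raw
weight is $1/f_c$, and weights are rescaled to mean 1 so they modulate the
loss without changing its overall scale. Second, the focal loss

$$\mathrm{FL} = -\alpha_t (1-p_t)^{\gamma} \log p_t,$$

with $p_t$ the predicted probability of the true label and $\alpha_t$ the
class weight of the element's channel. The modulating factor
$(1-p_t)^\gamma$ suppresses the millions of easy background pixels and
concentrates gradient on hard boundary pixels; $\gamma = 2$ by default,
$\gamma = 0$ recovers weighted cross-entropy. Probabilities are clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-7}$ before the
logarithm — purely numerical safety.

This loss is often presented in a categorical form, but with sigmoid
outputs and overlapping classes the only consistent formulation is the
per-channel binary focal loss, which is what this package uses.

The learning rate follows polynomial decay,

$$\mathrm{lr}(s) = (\mathrm{lr}_0 - \mathrm{lr}_{end})
\left(1 - \tfrac{s}{S}\right)^{p} + \mathrm{lr}_{end},$$

stepped once per epoch ($s$ = 0-based epoch index, $S$ = `decay_steps`,
default the epoch count). Defaults $\mathrm{lr}_0 = 10^{-3}$,
$\mathrm{lr}_{end} = 10^{-5}$, $p = 1$ are conventional, not prescribed;
the optimizer is Adam, likewise a conventional default exposed through the
configuration rather than a claim.

## Metrics and protocols

Per class, the package reports pixel accuracy, the Dice coefficient
$D = 2|S\cap G| / (|S| + |G|)$, and the Jaccard index
$J = |S\cap G| / |S\cup G|$; the two satisfy $J = D/(2-D)$, which the
tests check to $10^{-12}$ as an algebraic cross-validation of both
implementations. Two conventions required decisions the formulas do not
make:

* **Both-empty masks score 1.** A correct "nothing present" prediction
  should not be penalized.
* **The combined objective** — mean Dice plus mean Jaccard over the test
  set, a value in $[0,2]$ — reduces each image's multi-class D and J as the
  mean over the *structure* classes, excluding background. Including the
  dominant background channel would inflate the objective with trivial
  agreement. Background metrics are still reported per class.

Because "accuracy" over a 4-channel multi-label stack is ambiguous, the
report carries per-class accuracy, all-channel accuracy, and
structure-only accuracy side by side.

Validation protocols: an 80:20 hold-out split and stratified k-fold
cross-validation (default $k = 10$). All segmentation classes appear in
every image, so there is no natural categorical label to stratify on; the
package stratifies on quantile bins of the clavicle pixel fraction — the
rarest class is the one a split can most easily unbalance. This scheme is
a documented stand-in, configurable via `stratify_by_class_fraction()`.
Fold assignment deals shuffled identifiers through a single rotating
cursor, one stratum at a time, so fold sizes differ by at most one both
globally and within every stratum. `paired_t_test()` compares two methods
on per-sample scores using the exact t distribution — fold counts are
small, so a normal approximation would be inappropriate.

## Augmentation and splitting

Augmentation adds exactly one rotated copy per image, the angle drawn
uniformly from $[-5°, 5°]$ with exact zeros re-drawn (so a 246-image corpus
becomes 492). Images rotate bilinearly, masks with nearest-neighbor about
the frame center, frame size preserved and uncovered corners filled with
black, matching radiograph borders. Augmentation precedes splitting, so
`split_dataset()` groups every rotated copy with its source sample and
assigns the group as a unit — otherwise near-duplicates would leak across
the train/test boundary. With singleton groups the test set size is exactly
`round(fraction · n)`; with grouped samples it can deviate by up to one
group, the price of the leakage guard.

## The phantom generator

`generate_phantom()` draws, on a configurable canvas: two large bright lung
ellipses, one medium heart ellipse overlapping a lung, and two thin tilted
clavicle bars at **half** the lung contrast, plus additive Gaussian noise
clipped to $[0,1]$. Centers, axes, and angles get mild seeded jitter so
datasets have the inter-sample variability that augmentation, splitting,
and stratification need. Ground truth is exact by construction, pixel
counts are always ordered lungs > heart > clavicles, the background channel
is the exact complement of the structure union, and identical seeds give
bit-identical output.

What the phantoms emulate: the class-imbalance hierarchy, structure
overlap, a hardest low-contrast class, and noise. What they do not:
anatomical texture, rib cages, exposure variation, pathology, or the
scale (2048×2048) and subtlety of real radiographs. Tests passing on
phantoms therefore demonstrate that the machinery — operators, gradients,
bookkeeping, protocols — is correct and that the model class can recover
known geometry; they do not certify clinical performance, and notably the
*advantage* of edge enhancement seen on real radiographs need not
reproduce on high-contrast phantoms, where the baseline already saturates.

## Problem sizes and numerical choices

The bundled experiments run at deliberately small scale so that the whole
suite executes on a single CPU core: 64×64 phantoms, a depth-2 U-Net with
8 base filters (~55k parameters), 32 training images, and ≤ 50 epochs for
the hold-out recovery experiment (about 400 optimizer steps; the two-fold
smoke run uses batch 2 × 100 epochs to reach the same step budget on its
8-image training halves). At these sizes lung Dice on held-out phantoms
reliably exceeds 0.9. Key numerical conventions, in one place:

| choice | value | note |
|---|---|---|
| conv border default | replicate | no spurious frame edges |
| magnitude normalization | per-image min–max | constant maps go to zero |
| focal clamp ε | 1e-7 | inside the log only |
| pooling tie-break | first maximum in scan order | deterministic backward |
| binarization | strict `>`, default 0.5 | at-threshold maps to 0 |
| both-empty D/J | 1 | correct negatives not penalized |
| weight init | He normal, zero biases | seeded via config |
| rotation fill | 0 | black radiograph border |
| mask resize/rotation | nearest-neighbor | stays binary |

## Limitations

* No GPU path and no mini-batch vectorization across images; training
  beyond a few hundred small images becomes slow.
* DICOM and the raw 2048×2048 big-endian radiograph format are out of
  scope; inputs are PNG/TIFF.
* Augmentation is rotation-only by design; elastic or intensity
  augmentation is not implemented.
* The stratification criterion and the multi-class reduction inside the
  combined objective are documented package choices where the underlying
  procedure is ambiguous.
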