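---
title: "From classifier attributions to tumour masks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From classifier attributions to tumour masks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xaiseg)
```

## The idea

A classification network trained to answer "does this slice contain a
tumour?" compresses the slice into a latent representation that must encode
the tumour's presence — and, because convolutional features are spatial,
largely its location. Attribution methods act as surrogate decoders of that
representation: they map a class score back onto the input pixels. `xaiseg`
operationalises this as a weak segmenter: attribute the *tumour class*
(always class 1, not the predicted class — the object of interest is the
tumour even when the classifier errs), normalise the attribution map,
binarise and regularise it, and score the result against ground truth.

## The attribution methods and their math

Let $y_c$ be the class-$c$ logit, $x$ the input, $A_k$ the $k$-th activation
map of a named stage.

* **Saliency**: $|\partial y_c/\partial x|$.
* **Input × gradient**: $|x \odot \partial y_c/\partial x|$.
* **Guided backpropagation**: plain backprop, except at every rectifier
  gradient passes only where the forward pre-activation is *strictly*
  positive and the incoming gradient is *strictly* positive. A tie at
  exactly zero blocks the gradient: the subgradient at the kink is not
  defined, and blocking gives a deterministic, conservative rule. On a
  rectifier-free network the rule never fires, so the map equals saliency —
  a property the test suite asserts.
* **Grad-CAM**: $\alpha_k = \operatorname{mean}_{ij}\,
  \partial y_c/\partial A_k^{ij}$, map $= \mathrm{ReLU}(\sum_k \alpha_k
  A_k)$, upsampled bilinearly to the input size. Non-negative by
  construction. The default stage is the last rectified convolutional stage
  (`relu4`), the standard choice: the deepest layer that is still spatial.
* **Guided Grad-CAM**: elementwise product of the two *pre-normalisation*
  maps, then one normalisation. Products of independently normalised maps
  would weight the components arbitrarily.
* **Occlusion**: slide a window (default 16×16, stride 8, baseline 0 —
  covering a 64×64 input in 49 forward passes); each placement records the
  drop in $y_c$ when the window is replaced by the baseline; a pixel's raw
  attribution is the mean drop over placements covering it.
* **Feature ablation**: the same drop measured per arbitrary pixel group;
  with single-pixel groups it is exactly occlusion at 1×1/stride 1 (an
  equivalence the tests check bitwise).
* **Layer gradient × activation**: per-channel maps $A_k \odot \partial
  y_c/\partial A_k$ at native resolution. No automatic channel reduction is
  applied: channel choice is inherently manual for layer methods, so the
  API makes the selection explicit (`as_heatmap(la, channel = k)`).
* **Neuron gradient**: $|\partial a/\partial x|$ for one named activation;
  addressing the target-class output unit reproduces saliency.

**Normalisation.** Every input-level heatmap is the per-image min-max
normalisation of channel-maximum absolute attributions. Maximum (not mean)
across channels preserves thin, single-channel structures. Min-max (rather
than division by the max) is what makes a *fixed* downstream threshold
meaningful across methods with very different raw scales; a map whose raw
attributions are all equal carries no spatial information and is normalised
to all zeros by convention.

## The classifier and its engine

No deep-learning framework is assumed: the package ships a small CNN engine
(im2col convolutions over BLAS, 2×2 max pooling with a deterministic
first-in-scan-order tie-break, global average pooling, a linear head) with
exact analytic backprop in double precision. This is what makes the
attribution contract *checkable*: the suite verifies analytic gradients
against central finite differences at $10^{-3}$ tolerance and observes
agreement around $10^{-11}$.

The test backbone (`tiny_cnn_backbone()`) has four conv/ReLU/pool stages and
defaults to 64×64 single-channel inputs — four pooling stages still fit, the
phantom tumour spans several feature-map cells, and a 200-slice training run
takes under a minute on one CPU core; larger inputs are a constructor
argument away. `adapt_backbone()` mirrors the transfer-learning workflow:
it replaces only the final dense head (with a seeded fresh initialisation)
and leaves every other parameter untouched.

Training is Adam (default lr 3e-3, batch 16, 12 epochs, 80/20 split) on
softmax cross-entropy. The optimiser, split and batch order derive from one
seed, and the engine has no nondeterministic operations, so two runs give
bit-identical losses. The defaults are declared configuration, not tuned
reproductions of any published training run.

## Postprocessing: faithful by default

`process_mask()` composes: grayscale (luminance weights 0.2125/0.7154/0.0721,
alpha dropped first) → threshold (`value <= 0.35` is background — the
boundary pixel goes to background) → component filtering (4-connected
components under 10 px removed; survivors dilated 3×3 after a neighbour-count
convolution whose "sum exceeds component size" guard is mathematically always
true for non-empty components and is kept purely for fidelity) → hole filling
and 5×5 elliptical closing (dilation treats outside-frame as background,
erosion as foreground, so closing has no frame artefacts) → convex hull of
foreground pixel coordinates, rasterised inclusively.

Two deliberate quirks are preserved in the default `"faithful"` mode: the
cluster and closing stages are computed but do **not** feed the final hull,
which is taken over the *thresholded* image's foreground. Whether the hull
was ever intended to consume the cleaned mask is unknowable from the
reference pipeline, so the package exposes both: `"cleaned"` mode hulls the
filled-and-closed mask instead (an isolated suprathreshold speck then no
longer drags the hull toward it; the vignette's corresponding test
constructs exactly that contrast). Fewer than three foreground pixels, or a
collinear set, yield an empty mask — a convex hull degenerates there, and
an empty mask is the honest output.

Numerical conventions: arrays are (row, col) with origin top-left; hull
vertices are converted to (x = col, y = row) before polygon filling;
boundary pixels are included (a point-on-edge test with an exact
integer-arithmetic cross product backs the crossing-number test). Dice/IoU
define 1.0 for two empty masks: a tumour-free slice correctly predicted
empty is a success, not undefined.

## The phantom generator: what it does and does not emulate

`generate_phantom()` draws a head (random ellipse, semi-axes 70–100 px on a
240×240 slice, smooth three-wave sinusoidal texture of amplitude 0.12 around
base 0.35), and optionally a tumour: a random ellipse (semi-axes 12–28 px)
with a low-amplitude sinusoidal radial perturbation (±15%, 3–6 lobes) so the
blob is compact but not convex — the hull step visibly does work. The
tumour adds 0.45 intensity; Gaussian noise (sd 0.05) is added and the image
clipped to [0, 1]. The mask marks exactly the tumour pixels; every tumour
pixel lies inside the head; placement retries until the blob fits. All
sampled geometry is stored in `$params` so tests can recount mask pixels
from the generating inequality independently.

These defaults make the two classes separable by construction (tumour/annulus
contrast ≥ half the added intensity, asserted per phantom) — deliberately:
the end-to-end suite is a *parameter-recovery* experiment, asking whether
the pipeline recovers a mask it should be able to recover. What the phantom
does **not** emulate: MRI physics, multi-modal acquisition, blurred
infiltrative boundaries, anatomical context correlated with the label, or
3D structure. Passing tests therefore show the machinery is correct and the
method works under its own assumptions; they do not predict clinical-data
Dice.

## Problem sizes and numerical choices

The suites run at deliberately modest scale, chosen as the smallest sizes at
which each property is meaningful: gradient oracles on 16×16 inputs with a
4/4/8/8-channel backbone (20 random inputs, tolerance 1e-3, FD step 1e-5 —
large enough to dominate double-precision round-off, small enough that
rectifier kinks are rarely straddled); occlusion oracles at 32×32; the
end-to-end run trains on 200 phantoms at 240×240 (resized to 64×64 for the
network) for 12 epochs and evaluates 20 held-out tumour slices, with the
heatmap upsampled back to 240×240 before postprocessing — mirroring the
downscale-for-the-network / evaluate-at-native-resolution pattern used with
real slices. Under these conditions validation accuracy reaches 100% and
held-out mean Dice lands around 0.7–0.8 depending on the seed; the suite
asserts the property bounds (≥ 95%, ≥ 0.5), not the incidental values.

## Known limitations

* Faithful-mode masks are convex by construction; concave tumours are
  over-covered (the main Dice cost observed on phantoms).
* The per-image min-max normalisation means the 0.35 threshold is relative:
  a slice with no strong attribution anywhere still produces a full-range
  heatmap. On phantoms the classifier is confident, so this rarely bites;
  on ambiguous real slices it would.
* Layer/neuron methods require manual channel/neuron selection by design.
* The engine is CPU-bound plain R: fine for 64×64 test backbones, not meant
  for 512×512 production training.
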