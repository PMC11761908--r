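---
title: "Methods: a lightweight depthwise-separable U-Net pipeline for breast-lesion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight depthwise-separable U-Net pipeline for breast-lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`lwunet` classifies breast lesions as benign or malignant from two imaging
modalities — mammography (MGI) and ultrasound (USI) — pooled into a single
training set. The classifier is a nine-layer encoder/decoder network built
entirely from depthwise-separable convolution (DSConv) blocks:

* **DSConv block.** A 3×3 *depthwise* convolution (one kernel per input
  channel, stride 1, zero padding 1) extracts spatial structure per channel;
  a 1×1 *pointwise* convolution mixes channels; batch normalization and ReLU
  follow. A block with $C_\mathrm{in}$ inputs and $C_\mathrm{out}$ outputs has
  $C_\mathrm{in}K^2 + C_\mathrm{in}C_\mathrm{out} + 2C_\mathrm{out}$
  trainable parameters, versus $9\,C_\mathrm{in}C_\mathrm{out}$ weights for a
  standard 3×3 convolution; the multiply-count ratio is
  $1/C_\mathrm{out} + 1/K^2$.
* **Encoder.** Four DSConv blocks with output widths $C_0, 2C_0, 4C_0, 8C_0$,
  each followed by 2×2 average pooling, so the spatial resolution halves four
  times (inputs must therefore be divisible by 16).
* **Bottleneck.** One DSConv block expanding $8C_0 \to 16C_0$.
* **Decoder.** Four levels, each bilinearly upsampling 2×, concatenating the
  matching encoder feature map (skip connection), and applying a DSConv block
  that reduces channels: $24C_0\to 8C_0$, $12C_0\to 4C_0$, $6C_0\to 2C_0$,
  $3C_0\to C_0$.
* **Head.** Global average pooling over space followed by a fully-connected
  layer to two logits with softmax semantics.

Exactly nine DSConv layers execute in any instantiation. The forward and
backward passes are written in this package (the depthwise kernels in
compiled code, everything else as vectorized array algebra over BLAS), and
every analytic gradient is verified against central finite differences in
the test suite.

## Preprocessing

Images are resized to a standard square (256×256 by default; all sizes in
this vignette are configurable) by separable bilinear interpolation, then
intensity-normalized with a Box-Cox power transform
$y = (x^\lambda - 1)/\lambda$ ($\log x$ at $\lambda = 0$), $\lambda = 0.5$ by
default.

Two choices here were genuinely open and are fixed as follows:

* **Domain shift.** The power transform needs $x > 0$ but 8-bit pixels
  include 0. Each pixel $v \in [0,255]$ enters the transform as
  $x = (v + 1)/256 \in (0, 1]$. The map is deterministic, strictly monotone
  for every $\lambda$, and domain-safe.
* **Rescaling.** After the transform, each image is min-max rescaled to
  $[0, 1]$ *per image* (not per dataset): multi-source image collections
  carry source-level brightness offsets, and per-image scaling removes them.
  A constant image maps to all zeros.
* **Interpolation convention.** Bilinear resampling uses half-pixel-centered
  sample positions with edge clamping. This convention preserves the mean
  intensity and constant images, and is the common default in the image
  libraries of this stack; it is fixed and documented here because any
  consistent convention would do, but mixing two of them would silently
  shift pixels by half a cell.
* **Storage.** Normalized images are stored losslessly as float32 in a
  minimal documented container (`.f32`: three little-endian `int32`
  dimensions, then column-major little-endian `float32` values), because the
  available PNG writer is 8-bit and would quantize the transform.

## The synthetic data generator

No external image collection is bundled. Instead, `generate_dataset()`
emulates the *shape* of a two-modality benign/malignant dataset so that
every downstream stage is exercisable and testable:

* **Lesion geometry.** Benign lesions are smooth ellipses; malignant lesions
  have a spiculated boundary $r(\varphi) = r_\text{ellipse}(\varphi)\,(1 +
  a\cos(k\varphi + \phi))$ with $k \in \{8,\dots,12\}$ lobes — the canonical
  visual contrast between circumscribed and spiculated masses in breast
  imaging. Semi-axes are drawn uniformly from 0.14–0.22 of the image edge,
  spicule amplitude from 0.25–0.45 of the mean radius, with random rotation
  and phase. The amplitude floor and lobe-count cap are set so the malignant
  boundary signal survives the renderers' soft edges and speckle: a phantom
  whose class contrast blurs away at the modality's point-spread scale would
  not exercise the classifier.
* **Modality appearance.** MGI renders the lesion (+85 intensity, soft
  edges) on a fixed smooth low-frequency background with additive Gaussian
  noise (sd 8); USI uses a darker background (55) with a brighter lesion
  plateau (150) multiplied by unit-mean gamma speckle (shape 4). Outputs are
  clipped to $[0,255]$ and written as 8-bit RGB PNG (the grayscale render
  replicated to three planes, since the classifier consumes 3-channel
  input).
* **Balance and splitting.** Classes are exactly balanced per modality;
  train/test splitting (80:20 by default) is stratified by class×modality;
  everything is driven by a single seed and is byte-reproducible.

What the generator does **not** emulate: microcalcification clusters,
anatomic background texture, acquisition physics, BI-RADS morphology, or
inter-source heterogeneity. Passing tests on this data demonstrate that the
pipeline's mechanics (preprocessing, optimization, evaluation arithmetic)
are correct and that the classifier can extract a genuine morphological
signal — they say nothing about clinical performance on real mammograms or
ultrasounds. The built-in separability check (a threshold on boundary
irregularity, perimeter²/4π·area, classifies the generated training images
with ≥90% accuracy) guarantees the classes are learnable by construction.

## Training protocol

Training uses Adam with categorical cross-entropy on the two-logit softmax
head — the loss is this package's choice; it is the standard pairing for a
two-class softmax head. Defaults follow the published protocol this package
re-implements: learning rate $10^{-5}$, batch size 16 (32 for augmented
runs), 50 epochs, 5-fold cross-validation. The kernel size is 3 (the
architecture description; a table footnote elsewhere says 5 — the
architecture text wins, and the choice is exposed in the configuration).

The cross-validation protocol partitions **only the training split** into
$k$ folds, stratified by class×modality. Each fold trains on $k-1$ parts,
validates on the held-out part every epoch, snapshots the weights at the
best validation accuracy, and evaluates that checkpoint on the single fixed
test split. Per-fold metrics are averaged arithmetically per class; the
overall row is the mean of the two per-class averages. Validation curves
come from the fold's held-out portion, never from the test split.

Other fixed numerical choices: no convolution biases (BN provides the
shift); BN $\epsilon = 10^{-5}$, running-statistics momentum 0.1, biased
(population) mini-batch variance; He initialization; Adam moments 0.9/0.999,
$\epsilon = 10^{-8}$; no weight decay, schedule, or early stopping. Global
seeding covers weight initialization, fold shuffling and batch order, so a
rerun is bit-identical.

### Desk-scale learning sanity

The test suite trains the classifier end-to-end on the synthetic dataset at
a desk scale chosen to finish in minutes on one CPU: 500 images per class at
64×64, base width $C_0 = 8$, 10 epochs, batch 16, and Adam's canonical
learning rate $10^{-3}$. The default $10^{-5}$ rate is calibrated to
50-epoch training on a five-figure image count; in a 500-step desk run it
moves He-initialized weights by $\sim 5\times 10^{-3}$ of their scale, which
cannot train any model — so the desk-scale rate is the conventional Adam
default instead. The run must reach ≥90% test accuracy; the class signal is
separable by construction, so this checks the whole learning path rather
than reproducing any published headline number (which would require the
original multi-source datasets and full-scale augmentation, both out of
scope).

## GAN-side computations

The augmentation side of the pipeline needs a handful of generic
ingredients, implemented and tested as free-standing operations:

* **AdaIN** $\mathrm{AdaIN}(x, y_s, y_b) = y_s\,(x - \mu_x)/\sigma_x + y_b$,
  with a $10^{-8}$ stabilizer on $\sigma_x$ so constant channels map to
  $y_b$ instead of dividing by zero.
* **Non-saturating logistic losses** for the discriminator,
  $L_\mathrm{real} = \mathbb{E}[-\log\sigma(D(x_\mathrm{real}))]$ and
  $L_\mathrm{fake} = \mathbb{E}[-\log(1-\sigma(D(G(z))))]$, evaluated through
  softplus so no logarithm argument can reach zero.
* **Feature matching**: the squared distance between mean discriminator
  features of real and generated batches, as printed (mean-feature
  matching, not per-layer matching, which the source formulation leaves
  unspecified).
* **Gradient penalty** $\mathbb{E}[(\lVert\nabla_{\hat x} D(\hat x)\rVert -
  1)^2]$ on uniform interpolates between real and fake samples.
* **Fréchet distance** between Gaussians fitted to image embeddings,
  $\lVert\mu_r-\mu_g\rVert^2 + \mathrm{Tr}(\Sigma_r + \Sigma_g -
  2(\Sigma_r\Sigma_g)^{1/2})$. The matrix root is taken by
  eigendecomposition of the symmetrized product
  $\Sigma_r^{1/2}\Sigma_g\Sigma_r^{1/2}$; eigenvalues below
  $-10^{-8}\max(1,|\lambda|_{\max})$ raise an error, smaller negatives
  (sampling noise) are clamped to zero, and the score is clamped at zero.

**Embeddings are pluggable and download-free.** The standard Inception
embedding would require a pretrained network this package deliberately does
not depend on; the default embedding is raw pixels (optionally resized and
channel-averaged to keep the covariance small), and a trained model's
encoder+bottleneck with global pooling is available as an alternative.
Consequently the package's Fréchet scores live on the pixel-embedding scale
and are not comparable to published Inception-based FID values.

**The mini-GAN is plumbing, not a contribution.** To exercise the losses in
an actual adversarial loop, `train_mini_gan()` trains an MLP generator
(latent → 128 → 256 → pixels, sigmoid) against an MLP discriminator
(pixels → 128 → 64 → 1, leaky-ReLU) on small grayscale images. MLPs were
chosen over small convolutional stacks because the gradient penalty's
parameter gradient requires differentiating through the input-gradient
computation (double backprop); for a piecewise-linear MLP this has a compact
closed form — with activation masks held fixed (exact almost everywhere),
$\partial P/\partial W_l = s_l t_{l-1}^\top$, where $s_l$ is the usual
backward chain and $t_l$ the forward chain seeded by $\partial P/\partial g$
— which the tests verify against numerical differentiation. Loss weights
(feature matching 1, gradient penalty 10) and Adam settings
($\mathrm{lr}=2\times10^{-4}$, $\beta_1 = 0.5$) are exposed in the
configuration; they are the conventional defaults for gradient-penalty GANs.
The training loop checks that a pixel-embedding Fréchet trace falls from its
initial value over 500 steps on 32×32 ultrasound-like images — a smoke
property, not an image-quality claim.

## Evaluation arithmetic

Per-class precision, recall and F1 are one-vs-rest percentages from the 2×2
confusion matrix; accuracy is the diagonal fraction. Weighted averages use
class supports, macro averages are unweighted, and the two coincide exactly
on balanced test sets. When a denominator vanishes the metric is reported as
0 with a warning. Display rounding is 3 decimals for table-style values and
2 decimals for improvement deltas; raw values are always retained and
serialized. Fold aggregation is the arithmetic mean per class per metric,
with the overall row the mean of the two per-class averages.

The package bundles the published fold-wise metric tables of the study it
re-implements (as plain CSV under `inst/extdata/`) and reproduces their
Average/Overall rows and the improvement deltas between the real-data and
augmented-data experiments purely by this arithmetic; this is the package's
exact, deterministic acceptance surface, complementing the stochastic
learning check.

## Problem sizes used by the tests

Unit tests run on tiny tensors (≤ 8×8×4 for convolution oracles, 16–64 pixel
images elsewhere). The learning-sanity check uses 1000 images (500 per
class) at 64×64; the mini-GAN check uses 128 ultrasound-like training
images at 32×32 for 500 steps; Fréchet-distance draws use 200–300 samples.
These sizes are the package's own desk-scale choices: large enough that
every property being asserted is comfortably away from its noise floor,
small enough to run routinely.

## Known limitations

* The synthetic generator validates mechanics, not clinical performance;
  published headline accuracies on the original multi-source datasets are
  not reproduction targets of this package.
* Fréchet scores use pixel or encoder embeddings, not Inception features.
* Inference and training are CPU-only and single-threaded apart from BLAS;
  the implementation favors auditability (every gradient hand-derived and
  finite-difference-checked) over raw throughput.
* Checkpoints use R's native serialization with a JSON sidecar; they are
  portable across platforms but not across deep-learning frameworks.
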