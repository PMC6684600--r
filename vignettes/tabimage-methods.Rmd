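---
title: "From feature vectors to images: the tabimage method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From feature vectors to images: the tabimage method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The idea

Convolutional networks exploit the fact that neighboring pixels are
correlated.  Tabular omics data — a gene-expression vector, say — has no
such neighborhood structure: the columns of a samples × features table are
in arbitrary order, and convolving over them is meaningless.  `tabimage`
manufactures the missing structure.  It treats each *feature* as a point
described by its profile across the training samples, embeds those points
in a plane so that similar features land close together, and then renders
every sample as a grayscale image in which each feature's normalized value
is painted at its feature's pixel.  Correlated gene modules become
contiguous bright or dark patches, and a CNN can then do what it is good
at: extract local patterns.

Formally, with a training set $\chi = \{x_1,\dots,x_n\}$, $x \in
\mathbb{R}^d$, the feature set $G = \{g_1,\dots,g_d\}$, $g \in
\mathbb{R}^n$, is the transpose of $\chi$.  A fitted transformation $T$
maps any sample $x \in \mathbb{R}^d$ to an $m \times n$ feature matrix
$M$ (the image).  $T$ is learned from the training split only and is
immutable afterwards: validation and test samples are pushed through it
without refitting anything.

## The transformation, step by step

1. **Embedding.**  The $d$ feature profiles are placed in 2D by exact
   t-SNE (default) or kernel PCA.  t-SNE is exact, not Barnes–Hut: the
   embedded points are features, so their count is the dimensionality $d$
   (tens to a few thousand), well inside exact t-SNE's comfortable range,
   and the $O(d^2)$ gradient is both affordable and more accurate than a
   tree approximation.  Perplexity defaults to $\min(30, (d-1)/3)$ and is
   lowered automatically when $d$ is small; exactly duplicated profiles
   are jittered by $10^{-10}\,N(0,1)$ because the perplexity search
   degenerates on coincident points.  For kernel PCA the RBF width is set
   deterministically to the reciprocal of the median squared pairwise
   distance (the usual median heuristic, made reproducible); a linear
   kernel reproduces ordinary PCA exactly, which the tests exploit.
2. **Enclosing rectangle.**  The convex hull of the embedded points is
   computed, and the minimum-area enclosing rectangle is found by the
   rotating-calipers principle: the optimum has a side collinear with a
   hull edge, so sweeping the hull-edge orientations and taking the best
   axis-aligned bounding box in each rotated frame is exact.  Area ties
   between orientations are broken toward the smaller angle so the result
   is deterministic.  All-collinear embeddings raise a typed error that
   recommends kernel PCA or a jitter rather than silently perturbing the
   geometry — a silent jitter would make the fitted map irreproducible.
3. **Rotation.**  The plane is rotated by the negative rectangle angle so
   the frame is horizontal/vertical, as the convolution grid expects.
   Rotation is an exact isometry; the tests verify pairwise-distance
   preservation to $10^{-9}$.
4. **Discretization.**  Rotated coordinates are rescaled into an
   $m \times n$ grid (default $120 \times 120$) and rounded half away
   from zero to 0-based pixel indices, row 0 at the top (image
   convention, y flipped).  The two axes are scaled independently so the
   cloud fills the frame; preserving the aspect ratio instead would waste
   pixels and increase feature collisions, which is the scarcer resource
   here.  A degenerate span (all x or all y equal) maps to the central
   row/column rather than erroring, so one-cluster embeddings remain
   usable.  Features that round to the same pixel form a *collision
   group*; at render time their normalized values are averaged.  Pixels
   with no feature hold the background value 0 — black contributes
   nothing through ReLU convolutions, matching "no signal here".  For
   very high-dimensional inputs (full transcriptomes) a larger frame such
   as $200 \times 200$ keeps the averaging loss tolerable.

## Normalization

Image shades must lie in $[0,1]$, so features are min–max normalized with
statistics fitted on the training split only.  Two variants are kept:

* **norm1** treats features as independent and rescales each by its own
  training minimum and maximum.  A feature constant in training maps to
  0 by convention (avoiding 0/0 with a documented choice).
* **norm2** applies one shared affine map — shift by the global training
  minimum, divide by the global training range — which retains the
  relative topology of values *across* features at the price of wasting
  dynamic range on low-variance features.

Held-out values outside the training range are clipped to $[0,1]$: a
shade cannot leave the image gamut.  Which variant wins is an empirical
question, so both models are trained with identical seeds (a paired
comparison) and the one with the lower validation error is kept; an exact
tie goes to norm1.

## The classifier

The classifier is a parallel CNN: two branches, each a chain of four
blocks (2D convolution with same padding → batch normalization → ReLU →
2×2 max pooling), with *different* kernel sizes per branch (3 and 5 by
default) so two filter scales see the image simultaneously.  Branch
outputs are flattened, concatenated, passed through one fully connected
layer and a softmax head.  Defaults: 16/32/64/128 filters across the four
blocks, 128 fully connected units.  Each pooling halves the spatial size,
so a $b$-block branch needs a frame of at least $2^b$ pixels per side;
smaller frames are rejected at build time with the minimum feasible size
in the message.

Training is minibatch SGD with momentum (defaults $\eta = 0.01$, $\mu =
0.9$, batch 32), chosen as the plainest well-understood optimizer for a
model of this size; the softmax cross-entropy is the loss.  After every
epoch the validation error is computed in inference mode (batch norm
running statistics), and the weights of the best validation epoch are the
ones returned — so the returned model is never worse on validation than
the final epoch.  The layer arithmetic lives in C++ (im2col + BLAS for
convolutions; the batch-norm/ReLU/pool head of each block is fused into
one kernel, since materializing the intermediate full-resolution arrays
dominated runtime otherwise).  Everything is seeded: initialization (He),
batch shuffling, and therefore the entire trajectory are bit-reproducible
on a fixed BLAS.

Hyperparameters are tuned, when asked, by seeded random search over a
declared space — reproducible trial-for-trial, with an injectable
objective so a surrogate-based (e.g. Bayesian) optimizer can be plugged
in later without changing the interface.

## Synthetic benchmarks

The generators define the study conditions for the test suite; they are
first-class, tested code.

* **ringnorm** — the classic two-class 20-dimensional Gaussian problem:
  class 1 $\sim N(0, 4I_{20})$, class 2 $\sim N\!\big((2/\sqrt{20})\mathbf{1},
  I_{20}\big)$, balanced 50/50, 7400 samples at full scale.  The optimal
  (Bayes) rule is the exact log-density ratio and is implemented in
  closed form; on a draw of 10000 samples it misclassifies 1.15% — the
  irreducible-error reference against which pipeline accuracies are read.
* **Madelon-like** — informative features are Gaussian clusters on
  hypercube vertices with a parity (XOR-style) label, so no linear
  classifier beats chance while a shallow tree does; redundant features
  are exact random linear combinations of informative ones; the rest is
  Gaussian noise.  This emulates the *style* of the Madelon benchmark and
  makes no claim to reproduce the published instance.
* **Correlated blocks** — features within a block share a latent factor
  (pairwise correlation $\approx \rho$); optionally one block's mean is
  shifted in class 2.  With $\rho = 0.95$ this is the fixture for the
  neighborhood property: the embedding must place each block's features
  closer to each other (in pixel distance) than to other blocks'.  With
  $\rho = 0$ and a 2σ shift on 20 of 60 features it doubles as a
  near-separable "blob" benchmark for end-to-end learnability.

Splitting is 80:10:10 (sizes within one sample of exact), stratified by
default via largest-remainder allocation so per-class proportions are
preserved within one sample; stratification refuses classes with fewer
than 3 samples.

What the generators do *not* emulate: real omics data is heavy-tailed,
batch-affected, and has correlation structure far richer than
block-diagonal.  Passing tests on these fixtures demonstrates that the
machinery is correct and that the pipeline can learn when a learnable
signal exists — not that any particular accuracy will transfer to a real
transcriptome.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is unambiguous: the
ringnorm pipeline uses 2000 samples, a 64×64 frame, a slimmed network
(8/16/32/32 filters, 64 FC units) and 6 epochs, reaching ~96% test
accuracy against the 1.15% Bayes floor; the blob pipeline uses 500
samples, a 32×32 frame and a 2-branch × 2-block network.  The full-scale
7400-sample, 120×120, full-width configuration is the same code path and
is expected to close most of the remaining gap, at a runtime measured in
hours on one CPU.

Other fixed choices: batch-norm $\epsilon = 10^{-5}$ with running
statistics updated at rate 0.1; geometry tolerances $10^{-9}$;
rectangle angles reported modulo $\pi/2$; pixel rounding half away from
zero (R's `round` would round half to even); out-of-frame coordinates of
held-out samples clamp to the border pixel.  Conv biases are kept for
completeness although batch normalization makes them redundant.

## Known limitations

* Exact t-SNE costs $O(d^2)$ memory in the number of features; beyond
  ~5000 features use kernel PCA or reduce dimensionality first (feature
  selection is deliberately out of scope).
* The CNN is CPU-only by design; it is adequate at desk scale but not a
  GPU framework replacement.
* A feature map fitted on one training split is meaningless for data with
  different columns; the transformer refuses dimension mismatches but
  cannot detect semantically reordered features.
* Chromosome-location-based arrangements and multi-channel (multi-omics)
  images are out of scope.
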