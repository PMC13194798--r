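---
title: "Methods: multi-scale deformable attention classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale deformable attention classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(msdam)
```

This vignette is the package's own account of the model it implements,
the choices that were genuinely open, and what the synthetic test
protocol does and does not show.

## The model

The classifier consumes the four-level feature pyramid of a backbone CNN
(channel widths declared by the backbone adapter; the production recipe
assumes 256/512/1024/2048 from a 101-layer residual network, the bundled
test adapter emits a configurable small tuple). Each level is projected
by a 1×1 convolution + batch norm + ReLU to a common width, bilinearly
resized to the finest level's resolution \((H_r, W_r)\), and the aligned
maps are concatenated.

Deformability is an explicit offset-grid formulation rather than
deformable convolution: a single 3×3 convolution over the concatenated
map predicts, per pyramid level, an \((\Delta x, \Delta y)\) field passed
through \(s\cdot\tanh(\cdot)\), so every displacement is strictly inside
\((-s, s)\) with \(s = 0.12\) in normalized coordinates by default. The
base lattice \(x_j = -1 + 2j/(W-1)\) spans \([-1,1]\) inclusive
(align-corners convention: \((-1,-1)\) is the top-left pixel *center*,
which makes the lattice endpoints exact); offsets are added and the
result clamped to \([-1,1]\). Each aligned map is then evaluated at its
deformed grid by four-neighbour bilinear interpolation with fractional
weights \(u = x_p - \lfloor x_p\rfloor\), \(v = y_p - \lfloor y_p\rfloor\).
The operation is differentiable in both the map and the grid, so the
offset predictor is trained end to end; the analytic grid gradient
\(\partial v/\partial x_p = (1-v)(F_{10}-F_{00}) + v(F_{11}-F_{01})\)
is verified against central finite differences in the test suite.

The sampled maps are averaged (mean fusion is symmetric in the scales —
a property test permutes them), then refined by two multiplicative
attention masks computed from the fused map: a single-channel spatial
mask (3×3 conv → ReLU → 1×1 conv → sigmoid) and a squeeze-excitation
channel gate (global average pool → bottleneck of ratio *r* → sigmoid).
A 3×3 convolution + batch norm + ReLU produces the fused representation;
global average pooling, dropout and a linear softmax head produce class
probabilities. The pooled penultimate vector is exposed for probes and
for channel-level Shapley attribution.

## Open design points and how they were settled

Several details are not pinned down by the recipe the package follows;
each was decided once, and is exposed in configuration:

* **Offsets per scale vs shared.** One \((\Delta x,\Delta y)\) pair per
  pyramid level (8 offset channels for 4 levels), because sampling is
  applied per fused level; `per_scale_offsets = FALSE` gives a single
  shared field.
* **Fractional part, not absolute value.** The interpolation weights use
  \(u = x_p - \lfloor x_p \rfloor\); an absolute-value reading would be
  dimensionally wrong for interpolation and inconsistent with the
  gradient formula.
* **Out-of-range neighbours.** After clamping, the four integer
  neighbours are clipped to the map (border replication); zero padding
  would inject dark-edge artifacts into sampled features.
* **Zero-initialized offset conv.** Training starts from the identity
  sampler (\(\Delta \equiv 0\) ⇒ deformable sampling = plain bilinear
  resize, asserted to 1e-5), which stabilizes early training. A side
  effect worth knowing: exactly at \(\Delta = 0\) every sampling point
  sits on the lattice, where bilinear interpolation has a derivative
  kink; finite-difference checks are therefore run at a small nonzero
  offset field.
* **Attention widths.** SE reduction ratio defaults to 16 (clamped so
  the bottleneck has at least one unit in tiny models); the spatial
  branch's hidden width defaults to the projection width. No batch norm
  inside the spatial-attention branch.
* **Optimizer.** AdamW (decoupled weight decay 1e-4 applied uniformly to
  all parameters, including biases and batch-norm scales — at 1e-4 the
  distinction is negligible and uniformity keeps the update a single
  vector operation); `optimizer = "adam"` switches decay off-path. The
  cosine schedule is stepped per epoch with \(T_{max}\) equal to the
  total epoch count, so its endpoints are exactly `lr0` and `eta_min`.
* **Label smoothing × MixUp.** Smoothing is applied to each target inside
  each MixUp term; the combined loss
  \(\lambda\,CE(f(\tilde x), y_i) + (1-\lambda)\,CE(f(\tilde x), y_j)\)
  is linear in \(\lambda\) (property-tested). One \(\lambda\) is drawn
  per batch.
* **Checkpoint selection** is by lowest validation loss (not accuracy),
  evaluated each epoch with deterministic transforms.
* **Augmentation parameters not stated by the recipe** (perspective
  distortion 0.2 at p = 0.3, intensity scaling U(0.9, 1.1),
  brightness/contrast jitter 0.1) are declared mild defaults, not
  inferred values, and all are overridable in `aug_config()`.

## Data pipeline conventions

Deduplication hashes the decoded 8-bit RGB pixel buffer in a fixed byte
order, not the container bytes and not float-normalized values: the same
image saved twice (even across class folders) collapses to one record,
deterministically, with the lexicographically first path retained. The
patient ID is the filename stem up to the first underscore, the whole
stem if none. The splitter shuffles whole patient groups with the seed
and fills train, then validation, by image-count targets; test receives
the remainder. Zero patient overlap is re-verified programmatically
after assignment — the invariant is an assertion, not an assumption.
Which fractions a published split targeted (images or patients) is often
ambiguous; this implementation targets *image* fractions with
whole-patient granularity, so achieved fractions deviate when patients
contribute many images.

## The synthetic generator and what the tests show

`generate_dataset()` emulates the *structure* the pipeline assumes —
class folders, `<patient>_<idx>` filenames, several images per patient,
injected byte-identical duplicates, optional imbalance — with per-class
geometric signatures: each class places a distinct number of Gaussian
blobs (1–5) on a ring of distinct radius (3 radii; 5 × 3 coprime, so the
first 15 classes are unique), plus a per-patient spatial jitter and
per-image Gaussian pixel noise (default sd 0.05 on [0, 1]). Defaults are
3 classes × 4 patients × 2 images at 64×64 with 2 duplicates — large
enough to exercise every pipeline branch, small enough for seconds-scale
tests; the training smoke test uses 3 classes × 8 patients × 2 images at
32×32, which a tiny model (channel tuple 8/16/16/16, projection width
16) overfits to 100 % training accuracy in 30 epochs at learning rate
3e-3 — a deliberately scaled-down optimization problem whose point is
end-to-end gradient correctness, not generalization.

What passing these tests does **not** show: anything about real MRI.
The generator makes no attempt at MRI contrast physics, anatomy, scanner
artifacts, or the label noise of clinical data; classes are separable by
construction (a nearest-centroid baseline already beats chance, which is
itself a test). Published headline accuracies on the external dataset
are correspondingly out of scope; what the package reproduces exactly is
every metric derivable from that study's printed 508-sample test
confusion matrix, which ships as `brain_tumor_confusion()`.

## Metric conventions

Per-class metrics are one-vs-rest throughout; per-class "accuracy" is
\((TP+TN)/N\) and per-class kappa is one-vs-rest Cohen's κ with
\(p_e\) from the marginal products — these readings reproduce the
published per-class tables exactly (e.g. ganglioglioma κ = 0.908 from
TP=5, FN=1, FP=0, TN=502). Division-by-zero cases (a class never
predicted, or absent from the data) yield 0 with a `degenerate` flag,
never NaN. Macro averages are unweighted; micro averages pool one-vs-rest
counts, which for single-label data makes micro precision = micro recall
= overall accuracy (tested as an identity). ROC/PR/KS are direct
threshold sweeps with trapezoid integration; AUC agrees with `pROC` to
1e-10 in the cross-check test. Bootstrap CIs are percentile (2.5/97.5)
over resampled means; with 504/508 correct the 2.5th percentile lands on
500/508 = 0.98425, reproducing the published lower bound 0.9843.

## Numerical choices

Batch norm uses biased batch variance with eps 1e-5 and momentum 0.1
running statistics; evaluation mode uses the running statistics and is
exactly deterministic (dropout disabled). The softmax and the
cross-entropy are computed via the max-shifted log-sum-exp. Non-finite
losses abort training with a diagnostic rather than propagate. All
randomness — weight init, shuffling, augmentation, MixUp, dropout,
bootstrap, Shapley sampling — flows through R's global RNG seeded from
the relevant configuration field, so every result in the package is
reproducible from (inputs, seed).

## Known limitations

* All split images are held in memory during `fit_msdam()`; the training
  loop is built for desk-scale experiments, not the full external
  dataset (pure-R convolutions are roughly two orders of magnitude
  slower than a GPU framework).
* No pretrained 101-layer backbone ships with the package; the adapter
  contract accepts one, but the bundled default is the tiny trainable
  pyramid.
* Exact-duplicate detection only; no perceptual hashing.
* Shapley attribution explains the linear head over pooled channel
  groups (mean/zero-baseline imputation); it is not a pixel-space
  attribution, and Grad-CAM provides the spatial view instead.
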