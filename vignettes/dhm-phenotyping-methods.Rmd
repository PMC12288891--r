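---
title: "Methods: label-free single-cell phenotyping from quantitative phase images"
author: "dhmpheno authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free single-cell phenotyping from quantitative phase images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhmpheno)
```

## The measurement and the problem

Digital holographic microscopy (DHM) coupled to a microfluidic channel
records quantitative phase images of suspended cells in flow: each pixel
holds the optical path delay, in radians, that the cell imposes on the
wavefront — a proxy for local dry-mass content. A frame (natively 384 rows
by 512 columns here, values typically in the interval −2 to 6 rad) contains
several cells on a static instrument background. The biological question
this pipeline serves is phenotypic: epithelial cells in suspension are
round, compact and optically dense, mesenchymal cells are elongated,
spindle-shaped and flatter, and tumors populate the continuum between the
two. The pipeline turns raw frames into per-cell feature vectors, classifies
phenotypes, quantifies mixtures of known populations (spike-ins), and scores
intratumoral heterogeneity.

## Pre-processing model and its assumptions

Because lens, camera, illumination and channel are fixed within one capture,
the background is assumed *static per acquisition*. It is estimated once as
the per-pixel **median of the first 50 frames** (`estimate_background()`)
and subtracted from every frame without clipping. The median is robust to
the cells themselves: with on the order of a dozen cells per frame, any one
pixel is covered by a cell in only a few percent of frames. If fewer than
50 frames exist, all available frames are used and a warning is recorded.

Segmentation is deliberately simple, matching the high contrast of phase
imaging: foreground is the set of pixels **strictly above 0.8 rad** after
background subtraction; its **8-connected** components are cell candidates,
and each component's outer border is extracted by border following (holes
are ignored). Components are numbered by their first pixel in a column-major
scan, making the output order deterministic. Touching cells that merge into
one component are kept as one object — no watershed declumping is applied,
because suspended cells in flow are rarely in contact and any declumping
heuristic would add unquantified shape bias.

Only components whose **pixel area strictly exceeds 30 px** are kept (the
boundary case, 30 px exactly, is rejected; this strict reading is
unit-tested). Each survivor is stored with the **96 × 96** phase window
centred on the floor of its area centroid. Windows that would cross a frame
edge are dropped and counted as border rejections rather than zero-padded:
a truncated cell corrupts every size and shape feature downstream.
Coordinates are 1-based `(row, col)` with pixel centres at integers
throughout the package.

An open ordering question — whether the 0.8 rad threshold applies before or
after background subtraction — is resolved as *after*, since subtraction is
the first stage of the chain and thresholding raw frames would entangle the
instrument background with cell phase.

## The morphology feature bank

`compute_features()` evaluates a fixed 15-feature bank ("v1") per cell,
spanning three axes:

* **size** — pixel area, polygonal contour perimeter, equivalent diameter;
* **shape** — circularity $4\pi A/P^2$, best-fit-ellipse aspect ratio and
  eccentricity from second-order mask moments (with the $1/12$ unit-square
  pixel term, so a 1-px-wide bar has finite axes), solidity (area over
  convex-hull lattice area via Pick's theorem), extent;
* **phase content** — mean/max/sd of phase in the mask, optical volume
  (summed phase, the dry-mass proxy), phase skewness, the slope of the
  radial mean profile, and mean phase-gradient magnitude (a texture
  surrogate).

The perimeter is measured on the polygon through border-pixel centres. Two
consequences are documented rather than hidden: circularity of very small
thresholded blobs can marginally exceed 1 (pixel-count area vs
pixel-centre perimeter), and the digital-disk circularity at radius 10 is
≈ 0.92, not 1. Feature-bound filtering (`apply_feature_bounds()`) ships
with **no active default bounds**: published boundary values for such banks
vary by instrument, and silently dropping cells under unknown defaults
would be worse than passing everything through (the 30-px floor is already
enforced upstream).

## The convolutional embedding channel

An optional 512-dimensional embedding complements the morphology bank: each
patch is affinely mapped from [−2, 6] rad to [0, 1], replicated to three
channels, and passed through an 18-convolutional-layer residual network
(7×7 stem, four stages of two residual blocks at 64/128/256/512 channels,
global average pooling; no classification head). Patches are fed at their
native 96 × 96 — the network is fully convolutional, and upsampling would
only interpolate. Only **seeded-random weights** are available: weights are
He-scaled Gaussians drawn once from a recorded seed, making the channel a
deterministic random-projection feature extractor that runs with no
downloads and no shipped binaries; every output records its
`weights_source`. Residual sums are divided by $\sqrt{2}$ to keep activation
variance stable through depth. The test suite verifies that with this
channel concatenated to morphology features, well-separated populations are
still classified at ≥ 90% — the morphology bank carries the discriminative
signal, and the embedding must never degrade it.

## Classification

Four fixed configurations are provided, with no hyper-parameter search:
random forest (**100 trees**, unbounded depth), SVM (**RBF kernel, C = 1**,
one-against-one), k-NN (**k = 5**, Euclidean), and a single-hidden-layer
network with **100 units** trained on softmax cross-entropy. The network is
fitted with the standard R single-hidden-layer implementation (`nnet`,
full-batch BFGS, 200-iteration cap, seeded initialization); the classifier
contract here is the architecture, not the optimizer. Features are z-scored
using training-fold statistics only (svm/knn/nnet); trees see raw features.

Evaluation is **stratified 5-fold cross-validation** after **random
undersampling to the minority class** (`balance_classes()`): undersampling
avoids the accuracy artifacts of synthetic oversampling, and stratification
prevents degenerate folds. Balancing precedes fold assignment. Accuracy is
the plain fraction correct on the held-out fold; reports carry all five
fold values plus median and quartiles.

**Null calibration.** With labels independent of features (two balanced
classes, 1,000 cells), mean CV accuracy must sit in the permutation-null
95% band **[0.45, 0.55]**. This band is wider than the naive binomial band
(±0.031) on purpose: held-out predictions share training data across folds,
which inflates the null standard deviation of CV accuracy by roughly a
third (measured ≈ 0.021 over 20 simulated permutation nulls at n = 1,000);
a binomial band would fail about a quarter of correct runs for the random
forest alone.

**Spike-in quantification.** `quantify_mixture()` trains on pure
populations only and reports predicted class fractions in a mixture. On the
default synthetic populations the acceptance suite requires the estimate
within 3 percentage points of truth at 25/50/75% mixtures of 1,000 cells.

## Embedding, dendrogram, heterogeneity

All samples of one comparison are z-scored and embedded **jointly** in one
2D UMAP fit (`n_neighbors = 15`, `min_dist = 0.1`, fixed seed, single
thread for exact reproducibility). Per-group density contours are bivariate
Gaussian KDEs (normal-reference bandwidth) on a common grid, with contour
levels at highest-density-region mass quantiles.

The **tumor heterogeneity score** of cell $i$ is
$d_i = \lVert x_i - c \rVert^2$, the squared distance of its embedding
coordinates to its own sample's centroid $c$; the per-sample mean of $d_i$
is the sample's score (the "Ø" score). "Cluster" here means the labelled
sample, not an unsupervised cluster. Two caveats are built into the design:
UMAP coordinates have arbitrary scale, so scores are comparable **only
within one fitted embedding** (the score is translation-invariant and
scales quadratically with coordinate scale — both are tested); and the
score could equally be computed in feature space, but the embedding space
is used because that is where the comparison is visualized. Group
comparisons are rank-based: Mann-Whitney (two-sided, normal approximation
without continuity correction, so permuted groups give p = 1 exactly) for
two samples; Kruskal-Wallis with Dunn's post hoc (tie-corrected z,
**Bonferroni** adjustment — the adjustment is a documented choice) for
more.

Sample dendrograms represent each sample by the per-feature **median** of
its cells over the **26 most important features** (impurity-based random
forest importance, descending, ties broken by name), then cluster samples
by **single linkage** on Euclidean distances — whose merge heights equal
the minimum-spanning-tree edge weights, an identity the tests verify
independently. The 26-feature default presumes the deep channel is present
(15 morphology + 512 embedding columns); with morphology alone the
pipeline uses all 15 and records the count, since requesting more features
than exist is an error by contract.

## The synthetic phantom generator

Because no instrument data ships with the package, every stage is validated
on synthetic phantoms with exact ground truth. A phantom cell is an
elliptical **parabolic phase dome**: peak phase at the centre falling to
zero on the ellipse boundary, rotated uniformly at random. This captures
exactly the axis the classifiers must separate — footprint size, axis
ratio, and phase height — while making no claim of optical realism (no
diffraction, no reconstruction artifacts, no internal texture). Defaults,
chosen once as plausible for suspended tumor cells at DHM-typical pixel
scales and documented here rather than fitted to anything:

| population | equiv. radius (px) | axis ratio | peak phase (rad) |
|---|---|---|---|
| epithelial | 11 ± 1.2 | 1.15 ± 0.10 | 2.6 ± 0.30 |
| mesenchymal | 8 ± 1.0 | 3.0 ± 0.45 | 1.8 ± 0.25 |
| hybrid (optional) | 9.5 ± 1.1 | 1.9 ± 0.35 | 2.2 ± 0.30 |

Scenes share one static background per stack (three low-frequency cosine
products of 0.3 rad plus six localized blemishes of ±0.4 rad), add
per-pixel Gaussian noise (default sd 0.05 rad), and place cells at integer
pixel centres under a 36-px minimum separation with a 52-px margin — the
margin keeps every default cell's footprint and its 96 × 96 window inside
the frame. Placement on the integer grid makes the dome-centre pixel value
analytically exact (background + peak) in noiseless tests. Spike-in scenes
allocate class counts **deterministically** — exactly
`round(p * n)` mesenchymal cells, round-half-even — so mixture-recovery
tests have exact ground truth rather than Bernoulli noise.

What passing tests on phantoms does and does not show: they verify the
pipeline's arithmetic, contracts and statistical behaviour end to end; they
do not certify accuracy numbers on real DHM data, whose backgrounds drift,
whose cells touch, and whose morphology distributions are unknown to the
generator.

## Numerical choices and degenerate inputs

* Strict inequalities at both filters (phase > 0.8; area > 30 px), boundary
  cases unit-tested.
* Masks below 3 px fail feature QC with a reason instead of yielding NaNs.
* Zero-variance feature columns are centred but not scaled during
  z-scoring.
* Singleton samples score $d = 0$ with a warning; degenerate (coincident)
  KDE groups are skipped with a warning.
* k-NN at k = 5 on two classes cannot tie in voting; for more classes the
  underlying implementation's tie handling applies and determinism given
  data order is tested.
* Per-stage seeds derive from the global seed by a polynomial string hash
  modulo $2^{31}-1$ (`derive_seed()`), so any stage can be re-run in
  isolation with the same stream.
* Frames are written as 16-bit TIFF with an affine phase scale in a JSON
  sidecar (quantization ≈ 1.2 × 10⁻⁴ rad over the −2..6 rad range);
  in-memory pipelines are exact, and byte-identical reproducibility is
  asserted on the CSV artifacts.

## Problem sizes used by the test and acceptance suites

Unit tests run on scenes of a few dozen cells in reduced frames. The
acceptance suite uses the study-scale designs: 1,000 cells per pure
population and per mixture for spike-in recovery; 504 cells at 0.05 rad
noise for segmentation recall; 1,000 cells for classifier null calibration;
2,000 cells for the end-to-end byte-identity check. These sizes are the
package's chosen validation scale: large enough that fraction estimates
resolve sub-percent differences, small enough to run routinely.

## Known limitations

* The morphology bank is a canonical reconstruction, not a verified port of
  any instrument vendor's feature list; numerical equivalence to any
  specific published feature table is explicitly not claimed.
* Pretrained natural-image weights for the embedding channel are not
  shipped; the seeded-random channel is a projection, not a learned
  representation.
* Background drift within an acquisition is not modelled (static-background
  assumption), and touching cells are not declumped.
* Heterogeneity scores are not comparable across separately fitted
  embeddings, by construction.
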