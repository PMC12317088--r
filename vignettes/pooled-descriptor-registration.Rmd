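---
title: "Feature-based multi-modal registration with pyramid average-pooling descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based multi-modal registration with pyramid average-pooling descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolreg)
```

## The problem

Serial tissue sections are routinely imaged with modalities that see
completely different physics: H&E histology shows morphology,
MALDI mass-spectrometry imaging maps lipids and metabolites per m/z
channel, LA-ICP mass-spectrometry imaging maps elements such as Fe, Zn
or Au. Overlaying them requires estimating the 2D affine transform that
takes the *moving* image into the coordinate frame of the *fixed* image.
Intensity values are not comparable across such modalities — bright in
one can be dark or mid-grey in the other, and each has its own noise
character — so registration must rely on *structure*: where intensity
varies, not what its absolute value is.

`poolreg` implements an unsupervised, learnable-parameter-free
feature pipeline for this task: dense hierarchical average-pooling
descriptors, a feature-magnitude map with distance-regulated keypoint
selection, Lowe-ratio descriptor matching, robust perspective-consistency
filtering, and a least-squares affine fit. Dice, Hausdorff and
mutual-information metrics quantify the result.

## The descriptor

For a pixel `(u, v)` take the square working window of side $W$ centred
there. Layer $l$ of the pyramid partitions the window into $2^{l-1}$
equal blocks (layer shapes $1\times1$, $1\times2$, $2\times2$,
$4\times2$, continuing by splitting the currently-coarser axis); each
block contributes its mean intensity

$$\bar I = \frac{1}{|B|}\sum_{(u,v)\in B} I_{u,v}.$$

All block means over layers $1\dots L$ are concatenated, and then the
single layer-1 (whole-window) mean is removed from the vector and
subtracted from every remaining entry. The descriptor therefore has
length $2^L-2$, captures only *relative* intensity structure inside the
window, and is exactly invariant (up to floating-point rounding) to a
constant intensity offset. Averaging over blocks also damps pixel
noise: the variance of a block mean shrinks with block area, which is
why the pipeline tolerates the noisy single pixels typical of MS
imaging.

Two geometry details are deliberate choices the method itself does not
dictate, isolated behind `pool_blocks()` so they can be swapped:

* the split-axis order of the block grids (columns first);
* non-divisible windows round block boundaries to equal fractions, so
  blocks may differ by one pixel in extent — arbitrary window sizes stay
  legal.

The **feature magnitude map** stores the Euclidean norm of the
descriptor at every interior pixel (a border of `ceiling(W/2)` pixels is
excluded because the window would not fit; computed exactly with
summed-area tables). High values mark high local intensity variation.
**Keypoints** are selected greedily in descending magnitude under
*distance regulation*: a candidate is accepted only if its minimum
distance to all previously accepted points exceeds $D$, enforced by
masking a disc of radius $D$, until $N$ points are accepted. Ties in
magnitude break by row-major scan order so runs are reproducible.

Defaults, all overridable through `pyramid_config()`: $W = 32$ px,
$L = 4$ (descriptor length 14), $D = W/2 = 16$ px, $N = 500$. $W$ sets
the structural scale the descriptor sees; $D$ trades keypoint density
against spatial coverage; $N$ caps the matching cost.

## Matching and the transform

The correlation matrix $H$ holds the Euclidean distance between every
moving descriptor (rows) and every fixed descriptor (columns). For each
row the two smallest distances are compared and the best match is
accepted iff

$$H_{[0]} \le 0.75 \, H_{[1]},$$

the Lowe ratio test: a match is trusted only when it is clearly better
than the runner-up. Equality counts as acceptance. When several moving
keypoints claim the same fixed keypoint, only the closest pair is kept
(the test is row-wise, so something must arbitrate; smallest distance is
the obvious policy).

Matched features on two planes of the same scene must be related by a
plane-to-plane perspective transform, so a seeded random-sample
consensus fits homographies to minimal 4-pair samples (normalized DLT)
and keeps the model with the most pairs under a 3 px reprojection
threshold (2000 iterations, seed 0; all exposed). Only the inlier pairs
reach the final stage: the affine transform minimizing the summed
projection error

$$D_{proj} = \sum_i \lVert P_F^i - M \, P_M^i \rVert$$

solved by QR decomposition (never normal equations — conditioning on
near-collinear point sets). Internally points are homogeneous column
vectors; the row-vector convention $P \cdot M$ seen elsewhere is the
transpose of the same map and minimizes the same error.

## Pipeline-level robustness

Four devices wrap the core matcher in `register_images()`. Each is a
design decision of this package, documented here because the core
method alone does not pin them down:

* **Descriptor polarity** (`polarity = "auto"`). The descriptor is
  linear in intensity, so a contrast-inverted modality negates every
  descriptor while leaving the magnitude map — hence detection —
  unchanged. Matching is attempted with the moving descriptors as-is
  and negated; the polarity with the larger consensus wins.
* **Unit-norm matching copies.** A monotone intensity remap between
  modalities is locally affine; the descriptor is already offset-free,
  and dividing by its norm removes the remaining local gain difference.
  The pipeline therefore matches unit-normalized copies (distance on
  unit vectors is a monotone function of cosine similarity). The
  module-level `correlation_matrix()` keeps the plain Euclidean
  contract; keypoint magnitudes are untouched.
* **Coarse rotation search** (`rotation_search = 0, ±10, ±20, ±30`).
  The window is axis-aligned, so descriptor similarity degrades beyond
  roughly ten degrees of residual rotation. Pre-rotating a modality
  acquired at 90 degrees is standard practice; the pipeline generalizes
  it by scoring a small set of coarse pre-rotations with a fast 3-point
  affine consensus and keeping the best (scanning stops early once a
  hypothesis explains a clear majority of its candidate matches).
  Features whose window overlaps resampling fill are discarded — the
  fill edge is an artificial structure.
* **Warp refinement** (`refine = 3`). The moving image is resampled
  into the fixed frame under the current estimate and matched again; at
  near-identity residual the descriptor's rotation- and scale-induced
  localization biases vanish. Each pass re-collects correspondences by
  nearest projected keypoint, polishes them to sub-pixel precision at
  the local normalized-cross-correlation peak (quadratic interpolation;
  pairs whose patches cannot be aligned, NCC < 0.2, are dropped;
  NCC tolerates monotone remaps and uses the chosen polarity), and
  refits with trimmed least squares (residuals above twice the median
  are discarded, twice). Because a pass can drift into a wrong
  correspondence basin, every candidate transform — including the
  coarse fit — is scored by mutual information between the fixed image
  and the warped moving image over valid pixels, and the best-scoring
  transform is returned. Mutual information here is a *verification*
  metric for model selection among a handful of candidates, not an
  optimization objective.

Preprocessing before detection (both images, working copies): hotspot
clipping at the 0.99 quantile — intensities strictly above the quantile
are set to the quantile value, taming MS-imaging outlier pixels — then
min-max normalization to [0, 1]. The clip precedes normalization, since
a single hotspot would otherwise compress the entire dynamic range. The
quantile uses the linear-interpolation convention (`stats::quantile()`
type 7). Multichannel stacks (one image per m/z value) are collapsed to
a single registration channel first; the default is the per-pixel mean
(deterministic, bit-stable), `"pc1"` projects onto the first principal
direction, and stochastic embeddings can be plugged in through
`register_embedding()` with a mandatory seed.

## The synthetic generator

No external data ships with the package; `generate_pair()` produces
modality-shifted pairs with known ground truth. The fixed image is a
sum of Gaussian "tissue" blobs plus band-limited texture (coarse white
noise bilinearly upsampled), min-max normalized. The ground-truth
affine composes scale and shear, rotation about the image centre, then
translation. The moving image samples the fixed content through that
transform, then passes a monotone intensity remap — identity, gamma
(power 0.6), inversion, or an increasing 3-segment piecewise-linear
map — then additive Gaussian noise and optional salt hotspots.
Monotone remaps preserve structure while decoupling absolute
intensities, which is exactly the cross-modality gap the pipeline must
bridge; the remaps were chosen once to span gentle (gamma), adversarial
(inversion) and strongly nonlinear (piecewise) gaps.

`recovery_suite()` encodes the study conditions: 20 cases at
256×256, rotations uniform within ±30°, scales 0.9–1.1, translations
within ±15% of the frame, the four remaps and noise levels 0/2%/5% of
dynamic range cycled across cases, per-case seeds derived from the
suite seed. Each case reports the maximum displacement of the four
frame corners between recovered and true transforms (a conservative,
whole-frame error measure), mask Dice before and after, and match
counts per stage.

What the generator does *not* emulate — hence what passing tests do not
show: real tissue texture and stain variability, section-to-section
anatomical differences (adjacent sections are similar but not
identical), non-affine deformation from sectioning and mounting,
resolution differences between modalities, and spatially-structured
(non-i.i.d.) noise. Results on the fixtures bound the method's
behaviour under its own assumptions, not its field performance.

## Numerical choices and degenerate inputs

* Quantile type 7; clipping is idempotent exactly when the quantile
  lands on an order statistic, and never raises any intensity on
  re-application.
* Constant images: `normalize_intensity()` maps them to all zeros;
  `mutual_information()` warns and returns 0 (zero marginal entropy);
  descriptors are exactly zero, so flat regions produce no keypoints.
* Collinear keypoint configurations: the minimal-sample degeneracy test
  (triangle area) skips them in the consensus; a fully collinear match
  set raises a degenerate-geometry error, as does an affine fit whose
  design matrix is rank-deficient.
* The ratio-test boundary (equality) is an acceptance, matching the
  printed inequality.
* Masks are warped with nearest-neighbour interpolation so they stay
  binary; images default to bilinear.
* All randomness (consensus sampling, fixture generation) is seeded;
  identical inputs and seeds give bit-identical outputs.
* Mutual information uses equal-width bins over each image's min-max
  range and natural logarithms (nats). Hausdorff is computed on full
  foreground point sets — no percentile robustification — in pixels,
  scaled by `pixel_size` when physical units are wanted.

## Limitations

The magnitude map is a global ranking: with strongly inhomogeneous
contrast, one region's features can dominate selection and starve the
rest of the image (an optional per-tile normalization is a possible
extension, deliberately not enabled). The descriptor is neither
rotation- nor scale-invariant by construction; the rotation search and
warp refinement recover rotations up to the searched range (±30° by
default, plus quarter-turns via `rotate_moving`) and the scale range
exercised in the suite (0.9–1.1), but gross scale differences need
prior resampling. The transform model is affine only — non-rigid
tissue distortion is out of scope.

## Using the package

```{r example, eval = FALSE}
library(poolreg)

pair <- generate_pair(fixture_config(seed = 7, rotation = 12, scale = 1.05,
                                     translation = c(10, -5),
                                     intensity_remap = "gamma"))
reg <- register_images(pair$fixed, pair$moving)
glance(reg)                      # match counts, residuals, polarity
tidy(reg)                        # recovered pose parameters
corner_error(reg$transform, pair$truth, dim(pair$fixed))

warped_mask <- warp_image(pair$moving_mask + 0, reg$transform,
                          out_shape = dim(pair$fixed),
                          interpolation = "nearest") > 0.5
evaluate_registration(pair$fixed_mask, warped_mask,
                      pair$fixed, reg$warped)

autoplot(reg, fixed = pair$fixed)   # residual heat map
plot_matches(reg)                   # side-by-side matched pairs
```

Problem sizes in the shipped tests and in `scripts/acceptance.R` —
256×256 frames, 20 suite cases, 10 noiseless transforms, 200
descriptor-oracle windows — were chosen as the smallest sizes at which
the statistics of interest (corner error, Dice, oracle agreement) are
stable across seeds.

The command-line front end (`inst/cli/poolreg`) exposes the same
pipeline as `register`, `evaluate`, `fixtures` and `features`
subcommands over TIFF/PNG files with YAML/JSON configuration; flags
override config-file values, which override the defaults, and every run
echoes the effective configuration, seed and match counts into the
transform JSON so results can be reproduced bit-for-bit.
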