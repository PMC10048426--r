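---
title: "Methods: grain segmentation, features, classification and pricing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grain segmentation, features, classification and pricing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainscan)
```

`grainscan` measures the quality of milled rice from bulk photographs:
grains lying loose on a dark background are segmented individually,
described by geometry / colour / texture features, classified by variety,
and the predicted variety composition of a sample is converted into a price
estimate that exposes adulteration. This vignette explains each model and
the choices behind the tunable parameters; the package's tests compute all
the quantitative claims repeated here.

## The synthetic scene model

Real grain-image collections are hard to share, so the generator is a
first-class part of the package rather than a test fixture. A grain is a
rotated filled ellipse whose radius is modulated by a low-amplitude radial
sinusoid (relative amplitude drawn from U(0, 0.03) by default, frequency 2
or 3); this is the simplest shape family whose moment-fitted ellipse axes
are recoverable, which is what makes feature-accuracy tests possible. Body
colour is a per-variety RGB mean with i.i.d. Gaussian per-pixel noise, and
a grain carries a brighter "chalky" patch with a per-variety probability,
mimicking the partial chalkiness seen in real lots.

Scenes default to 2592 × 1944 px (a 5 MP sensor) with a dark-blue
background, RGB (20, 30, 90). The dark-blue choice mirrors practical
acquisition rigs: it gives strong grayscale contrast against pale grains
while still distinguishing grey/black debris. Placement is rejection
sampling under a Chebyshev keep-out of `min_gap` pixels (default 4), so
grains never touch; the renderer raises a placement error, reporting how
many grains it did place, if the canvas cannot hold the request.
Salt-and-pepper noise (default density 0.005) is applied last, after
compositing, as in a camera pipeline.

Each of the eight default variety profiles (BM, KB, TB, TKB, EK, HK, WK,
SM) is a synthetic stand-in, *not* measured rice biometry: lengths span
22–60 px and widths 13–17 px so that long-grain and short-grain classes are
separable mainly by geometry, with mild colour differences. Prices in
`default_price_table()` are likewise synthetic, ordered so basmati types
cost more than kolam types. Consequences for interpretation: a classifier
accuracy measured on these scenes shows the pipeline is *capable of*
exploiting geometry/colour differences, not that real varieties are this
separable — real lots vary by season and region, overlap heavily in
dimensions, and include broken grains and debris that the generator does
not emulate.

Determinism: every stochastic step draws from R's global RNG seeded once
per scene from the spec, so an identical spec reproduces identical image
bytes and ground truth.

## Segmentation

The chain is median filter → grayscale → Otsu threshold → erosion markers →
watershed → region extraction.

* **5 × 5 median filter**, per channel, reflect (symmetric) padding at the
  borders; implemented in C++ and tested against a literal sorted-window
  oracle. The median is the standard cure for salt-and-pepper noise from
  stray reflections.
* **Grayscale** by the luma weights 0.299/0.587/0.114, rounded to 8 bits.
* **Otsu's threshold** is computed from the 256-bin intensity histogram
  p(k). For every candidate t the lower class is k < t and the upper class
  k ≥ t, with class probabilities U₀, U₁, class means m₀, m₁, and
  between-class variance σ²_b(t) = U₀U₁(m₀ − m₁)². The smallest t attaining
  the maximum is kept (a strict-improvement update during the sweep yields
  the first maximiser). The full trace is retained in the returned object
  for inspection and plotting. Foreground is `gray >= thresh`: grains are
  brighter than the dark background, and the upper class is the k ≥ t one.
* **Markers** come from one pass of 3 × 3 binary erosion (borders count as
  background, so erosion is anti-extensive); the iteration count is a
  parameter for denser scenes. Components are labelled 8-connectedly and
  numbered in raster-scan order of their first pixel, so labelling is
  deterministic.
* **Watershed**: markers grow through the Otsu foreground over an
  inverted-grayscale terrain (bright grain interiors are deep basins).
  The region-growing itself is `EBImage::propagate`, the standard
  marker-based segmenter in R image analysis; the package contributes the
  marker construction, the terrain choice, and the contract checks (markers
  must lie inside the foreground; the label set is preserved).
* **Merged-grain rejection**: watershed cannot split grains that genuinely
  touch, so such blobs must be discarded. A region is rejected when its
  area exceeds `merge_factor` (default 1.8) × the scene's median region
  area *and* its solidity falls below 0.95. The convexity confirmation is
  needed because in a mixed-variety scene the largest legitimate grain is
  itself ~1.9× the median area; touching pairs are distinguishable because
  they form a concave waist, while single grains (jitter amplitude ≤ 0.04)
  stay near-convex. Regions under `min_area` (default 25 px) are dropped as
  specks. Both rejections are reported, not silent.

On synthetic scenes with `min_gap` ≥ 4 and noise ≤ 1% the chain recovers
every ground-truth grain with mean IoU ≈ 0.99 (the test suite asserts
count equality and IoU ≥ 0.8).

## Feature blocks

The default registry is 18 + 288 + 24 = 330 named features per grain; the
registry (names, bin count, angles, histogram mode) is serialised to JSON
beside every feature table so column meaning is reproducible.

**Geometry (18).** The boundary is traced with Moore neighbour tracing
(Jacob's stopping criterion); the perimeter uses corner-corrected chain
weights (0.980 axial, 1.406 diagonal, −0.091 per corner) plus π, the
Minkowski correction for measuring through boundary-pixel centres half a
pixel inside the true outline — without it, roundness of a digital disk
misses 1 by several percent. Length and width are the axes of the
moment-matched ellipse (4√λ of the eigenvalues of the second-order central
moments), deterministic and mask-based, rather than a contour least-squares
fit. Convex area is the pixel-centre rasterisation of the contour's convex
hull, which keeps solidity ≤ 1 exactly. Degenerate (line-like) masks raise
a typed error rather than producing infinities.

**Colour (288).** R, G, B, H, S, V histograms with 48 bins, bin index
`floor(value · 48/256)`. Hue is computed by the standard sector formula
(+360 wrap) and rescaled from [0, 360) to the 8-bit range so all six
channels share one binning; saturation is likewise scaled to [0, 255].
Histograms are computed over masked grain pixels only — the bounding box
contains background that would contaminate colour distributions — but a
`bbox` mode is available for comparability with bounding-box workflows.

**Texture (24).** The grey-level co-occurrence matrix is 256 × 256 (full
8-bit depth, independent of the histogram quantisation), counted at unit
offsets for 0°, 45°, 90°, 135° — offsets (0,1), (−1,1), (−1,0), (−1,−1) in
row/column order — over ordered pairs whose both ends lie in the grain
mask. It is neither symmetrised nor averaged over angles, so each angle
contributes its own six statistics: contrast Σ(i−j)²p, dissimilarity
Σ|i−j|p, homogeneity Σp/(1+|i−j|), angular second moment Σp², energy √ASM,
and correlation Σ(i−μᵢ)(j−μⱼ)p/(σᵢσⱼ) with moments from the marginals of
p. Correlation is defined as 1 when a marginal standard deviation vanishes
(constant crop). All six match literal double-loop oracles to 1e−10 in the
tests, and the 0°-vs-transposed-90° identity is asserted as a property.

## Classifier bench

Eight model kinds: multinomial logistic regression, decision tree, random
forest, single-hidden-layer perceptron, and SVMs with linear, polynomial,
RBF and sigmoid kernels. Scale-sensitive models (all but the trees) see
internally standardised features (zero-variance columns pass through
unscaled); the standardisation is stored in the fitted object so prediction
is self-contained. All stochastic fits are seeded: same data + spec + seed
gives identical predictions.

Cross-validation is stratified k-fold (default k = 10): within-class
shuffling followed by round-robin dealing guarantees per-fold class counts
within ±1 of the fair share. Metrics follow the confusion-matrix
identities — per-class precision TP/(TP+FP), recall TP/(TP+FN), F1 their
harmonic mean — with macro (unweighted) averages as the headline numbers,
because adulteration detection cares about minority classes; weighted
averages are also reported. ROC curves are one-vs-rest threshold sweeps
over the per-class scores with trapezoidal AUC (equal to the Mann–Whitney
statistic under ties); SVM per-class scores are the pairwise-coupling
probability estimates.

Feature selection ranks Gini importances from a tree model, normalised to
sum to 1, keeping the top 59 by default (a threshold mode exists); ties
break by registry order so selection is reproducible. Grid search
evaluates the full Cartesian product by CV mean macro-F1, first maximiser
wins. Random-forest hyperparameters are named in scikit-learn terms
(`n_trees`, `max_depth`, `min_samples_split`, `min_samples_leaf`) and
mapped onto `randomForest`'s knobs: `ntree`, `maxnodes = 2^max_depth`, and
node size `max(min_samples_leaf, ceil(min_samples_split/2))` — the R
implementation has no direct split-minimum control, so the two sample
minima share one knob. The MLP defaults (8 hidden units, weight decay
1e−3, 150 iterations) and the SVM `coef0 = 1` for polynomial/sigmoid
kernels are bench defaults chosen for stable convergence on standardised
feature tables.

## Price factors and adulteration

Grain weight is unknown from an image, so price uses the volume proxy
L·l² (length × width², px³). For per-variety counts c and prices p
(currency/kg):

* actual factor: Σ pᵢLᵢlᵢ²Nᵢ / ΣNᵢ from true counts,
* predicted factor: the same with predicted counts Mᵢ,
* unadulterated factor: pⱼLⱼlⱼ² of the majority variety j alone.

All three are per-grain averages; the printed summed convention (no
divisor, and a ΣN factor on the unadulterated term) is dimensionally
inconsistent across the three quantities, and the comparison "predicted vs
unadulterated" only makes sense when they share units — `per_grain = FALSE`
restores the summed convention for anyone who wants it. Majority ties go
to the higher-priced variety (the conservative choice for detecting
dilution of a premium product); when truth labels are absent the majority
is taken from the predictions and the actual factor is reported as
unavailable rather than fabricated. The adulteration flag fires when
|predicted − unadulterated| / unadulterated exceeds a margin, default 5% —
a compromise between classifier noise on pure samples and sensitivity to
~10% dilution; it is a parameter, not a calibrated constant. The
detection rate is the fraction of true minority-variety grains predicted
as any non-majority variety.

These satisfy, and the tests assert, the no-adulteration identity (pure
sample ⇒ actual = unadulterated), price-scale covariance (prices × c scale
all factors by c; the percent error is invariant), monotonicity in each
price, and mixture bounds (the actual factor lies between the cheapest and
dearest per-grain values present).

## Problem sizes and numerical choices

The test suite exercises full-size 2592 × 1944 scenes once (80 grains, the
standard per-scene count) and otherwise uses 320–640 px canvases with
12–20 grains; classifier tests use 240-grain tables (8 × 30) for 10-fold
CV and smaller toy tables for the bench properties — sizes at which the
whole suite runs in well under a minute per file while still covering the
full-resolution path. Ties are broken deterministically everywhere
(first maximiser in Otsu and grid search, registry order in feature
selection, first class level in prediction votes). Degenerate inputs —
single-intensity histograms, single-class training tables, empty masks,
one-pixel regions, absent test classes — raise typed errors or flags
rather than NaNs.

## Known limitations

* The generator renders smooth-bodied ellipse-like grains on a clean
  background: no broken grains, husks, dust, shadows, specular highlights
  or illumination gradients. Passing tests certify the pipeline's
  mechanics, not field robustness.
* Touching grains are removed, not split; heavily clumped samples will
  lose grains to the merged filter (the rejects are reported).
* The ~2-px-resolution limit of moment-based axes means features are
  unreliable below ~8 px grain width.
* Price factors are unit-free proxies; absolute price prediction would
  need a length-to-mass calibration per variety.
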