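---
title: "Methods: phenotype quantification, source selection, scene synthesis, and pseudo-label refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype quantification, source selection, scene synthesis, and pseudo-label refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosynth)
```

phenosynth builds auto-labeled fruit-detection datasets without manual
annotation. Its pipeline has four stages: quantify fruit phenotypes from
transparent-background sprite images; fuse the resulting pairwise distance
matrices into one 2-D feature space and pick optimal source-domain datasets
as density-cluster medoids; composite rule-governed synthetic orchard
scenes whose labels are exact by construction; and refine a detector's
pseudo-labels with an adaptive confidence threshold in a self-learning
loop. This vignette explains the models behind each stage, the parameters
that matter, and the choices made where the design was genuinely open.

## Phenotype descriptors

**Shape.** The outer boundary of the foreground mask (alpha >= 0.5,
largest connected component) is traced, lightly smoothed with a 3-point
circular moving average (half-width `smooth = 1`) to suppress
pixel-digitization staircase harmonics, and resampled by arc length to a
fixed `n_points = 128` positions. Fixing the length is required because
descriptor sequences are later compared by Pearson correlation, which
needs equal-length vectors. The boundary is treated as a complex sequence
`s(k) = x(k) + i y(k)` and its DFT coefficients
`a(u) = (1/N) sum_k s(k) exp(-i 2 pi k u / N)` are the Fourier descriptors.
Contours are oriented so the complex traversal has positive signed area,
which puts the dominant harmonic of a circle at `u = 1` (for a disc of
radius r centered at c, `a(0) = c_x + i c_y` and `|a(1)| = r`).

Two normalizations are available. The default `mode = "standard"` stores
`d(u) = |a(u)|/|a(1)|` for `u = 2..17`: dropping `a(0)` gives translation
invariance, the modulus gives rotation and start-point invariance, and the
division by `|a(1)|` gives scale invariance — each exact, which the test
suite verifies to 1e-6 under explicit transforms. `mode = "paper"` stores
`|a(u)/a(0)|`, the classical centroid-ratio normalization; note that it is
*not* translation invariant (the centroid term moves with the contour), so
it is provided for comparability, not as the default. Sixteen retained
terms is the conventional low-frequency budget: shape energy concentrates
in low harmonics while high ones mostly carry noise.

**Color.** Foreground pixels are converted from sRGB to CIELAB (D65,
2-degree observer). Each channel is divided into fixed 20-unit intervals
(L over [0, 100]; a and b starting at -128); per interval the pixel
fraction `Rate_i` and mean `Mean_i` are recorded, and the channel summary
is the weighted mean `sum_i Rate_i * Mean_i` with the analogous weighted
between-interval variance. The color dissimilarity between two sprites is
the Euclidean distance between their weighted Lab mean vectors, i.e. a
Delta-E between mean colors. The variances are stored for inspection but
deliberately excluded from the distance: one value per channel enters the
L2 form. Because synthesis is CIELAB-first and conversion to 8-bit sRGB
is the last step, a planted color center is recovered by this descriptor
to within a Delta-E of about 0.5 (quantization); tests allow 2.0.

**Texture.** Global texture statistics on foreground fruit images are
unreliable (uneven illumination, strong edge contrast), so `n_patches =
16` square patches of `patch_size = 32` px are sampled uniformly among all
positions whose footprint is at least 95% foreground, using an
integral-image count of candidate positions. Each grayscale (Rec. 709
luma) patch is summarized by a rotation-invariant uniform local binary
pattern histogram: 8 neighbors on a radius-1 circle (bilinear-interpolated
diagonals), uniform codes 0-8 by the number of ones, one bin for
non-uniform codes — 10 bins, L1-normalized, averaged across patches.
LBP thresholds neighbor-center differences, so it is invariant to
monotonic intensity scaling; what it discriminates is the *spatial
grain* of the texture, not its amplitude. Texture dissimilarity is
`1 - rho` of the aggregate histograms.

**Distances.** Shape and texture use the Pearson dissimilarity
`1 - rho` (range [0, 2]; `1 - rho` rather than `1 - |rho|` preserves
ordering). A zero-variance descriptor pair is defined as distance 0 when
the sequences are equal and 2 otherwise. Dataset-level matrices average
all cross pairs of image-level distances between two datasets
(`aggregate = "cross-pairs"`); averaging descriptors first is available
behind `aggregate = "descriptor-mean"` since either aggregation is
defensible and they differ only through descriptor nonlinearity.

## Source-domain selection

The three matrices live on incommensurate scales (shape and texture in
[0, 2], color in Delta-E units), so each is multiplied by
`scale_feature = max_range / own_range`, where a range is max minus min of
the off-diagonal entries. After scaling, all three ranges are equal —
exactly, which the tests assert to 1e-9. With a zero diagonal the
off-diagonal min convention coincides with including the diagonal; the
implementation documents and tests the off-diagonal reading.

Each scaled matrix is embedded in 2-D by classical (Torgerson) MDS via
`stats::cmdscale`: deterministic, exact for Euclidean-realizable inputs
(planar point sets round-trip to 1e-6), and reproducible across platforms
after a sign-fixing rule (each axis is flipped so its largest-magnitude
coordinate is positive). A stress-minimizing iterative MDS would add
stochastic initialization for no benefit at these problem sizes. Fusion
projects the shape embedding onto its first principal component (the x
axis) and the concatenated color + texture embedding onto its first
principal component (the y axis), columns centered, signs fixed as above.
This one-axis-per-block projection is the main information bottleneck of
the method: configurations where two groups differ along the *second*
principal direction of the color + texture block can collapse; this is
inherent to representing three feature spaces in two axes.

Clustering uses DBSCAN (hand-implemented; no DBSCAN package is among the
package's dependencies) with `min_samples = 4` and Euclidean
neighborhoods; noise is labeled -1. For `eps = "auto"` the package uses
the sorted 4-NN distance curve but *not* its knee: with clusters of
heterogeneous tightness and no noise tail, the maximum-deviation-from-
chord knee lands on the first within-cluster plateau jump and
underestimates eps by an order of magnitude, turning looser clusters into
noise. The default is instead `eps = 1.05 x` the 90th percentile of the
4-NN distances: up to 10% genuine outliers remain noise, while members of
tight and loose clusters alike stay density-reachable. Each cluster's
recommendation is its medoid — the member with the smallest mean distance
to co-members, ties broken by label order — matching the idea that the
best source dataset is the one closest on average to everything it would
serve.

## The synthetic-data generator

The generator exists so every stage is testable offline, and its defaults
are the package's study conditions. Fruit sprites are superellipse blobs
(`r(theta) = (|cos/a|^n + |sin/b|^n)^(-1/n)`) with seeded low-order radial
wobble, rendered at 256 x 256 RGBA. The superellipse family was chosen
because its harmonic content is analytically controllable: the disc limit
(exponent 2, aspect 1, wobble 0) is a single-harmonic test case for the
Fourier descriptor. Color fills are CIELAB-first with per-sprite channel
spread; lightness is modulated multiplicatively by a texture field
`(1 - contrast) * shading + contrast * grain`, where shading is
multi-octave value noise and grain is per-pixel. `contrast` is the grain
fraction — the quantity LBP actually discriminates — and `octaves = 0`
yields a perfectly flat fill whose LBP histogram is a deterministic delta
at the flat code. Backgrounds are three bands (sky / tree canopy /
ground) with noisy boundaries and a ground-truth region mask; the band
colors are chosen so the package's own threshold segmentation recovers the
mask to at least 90% pixel agreement.

The planted collection used in parameter-recovery tests contains 3 groups
of 5 species datasets (4 sprites each, 20 per group). Groups differ in
shape exponent (2.0 / 4.5 / 1.15), color center (Delta-E > 30 apart), and
texture archetype (flat / weak grain / strong grain). Within a group the
species form a symmetric collinear ladder in the CIELAB a channel
(offsets 0, -2, -1, +1, +2 times delta = 8), the center species first:
the middle of a symmetric collinear set remains the mean-distance
minimizer under any affine projection, so the planted medoid survives the
PC1 fusion. Two design notes from building this fixture: Pearson shape
distance ignores descriptor magnitude, so groups must differ in harmonic
*pattern* (exponent), not merely aspect ratio; and group ladders must stay
inside the sRGB gamut, since clipping compresses ladder ends and can
displace the medoid.

What the generator does not emulate: real lighting, specular highlights,
out-of-focus blur, within-fruit color gradients, leaves with real venation,
perspective, or the appearance statistics of any particular cultivar.
Passing tests therefore demonstrate the correctness and calibration of the
algorithms on controlled inputs, not field performance on real orchard
imagery.

## Scene synthesis rules

Scene composition follows a fixed rule hierarchy. The background is
threshold-segmented into sky / tree / ground (bright or blue-dominant
pixels in the upper 60% are sky; of the rest, green-dominant pixels are
tree; everything below the lowest tree row is ground), and the largest
connected tree component is the only legal fruit area. Fruit placements
sample centers uniformly from that region; each placement draws rotation,
scale (as a fraction of image height, default 0.10-0.18), and HSV
saturation/brightness multipliers (default 0.8-1.2). Leaves (default one
per fruit) follow the same mechanics with a downward-biased rotation band
(default +/- 60 degrees) as a proxy for branch growth direction, since
growth rules are described only qualitatively in the field.

Occlusion is controlled by rejection-resampling rather than post-hoc
cropping: a candidate placement that would push *any* already-placed
fruit's occlusion ratio above `max_occlusion = 0.5` is rejected and
redrawn; after 200 consecutive rejections the scene aborts with a classed
error carrying its audit log. The occlusion ratio of a fruit counts the
pixels of its binary footprint (alpha >= 0.5) covered by the union of
later-placed (higher z-order) sprites, divided by its footprint size — a
per-fruit bound, the stricter of the two possible readings (per fruit vs
scene average), and a zero-area footprint is defined as fully occluded.
Per-pixel bookkeeping during placement and final composition use the same
binary-footprint convention, so the emitted ratios match an independent
per-pixel recount exactly.

Labels are derived, not annotated: after alpha compositing in z order,
each fruit's visible mask is its footprint minus all higher-z footprints;
the bounding box is the tight box of that mask (exact by construction),
the polygon is the traced outline of the largest visible component, and
`area` is the visible pixel count. COCO output uses 0-based
`[x, y, w, h]` boxes and flattened polygon vertex lists; VOC XML uses
1-based inclusive corners, converted exactly. Everything is deterministic
in `(config, seed)`: a rerun reproduces byte-identical PNGs and
annotation files.

## Pseudo-label self-learning

A detector (any object implementing the infer/train contract; the package
ships a mock) is first trained on the synthetic set. Each round then
infers on the unlabeled target images, pools the confidence scores, and
selects the threshold maximizing the Otsu between-class variance
`sigma^2(t) = w0 w1 (mu0 - mu1)^2` over the grid `{0.01, ..., 0.99}`
(`grid_step = 0.01`; ties go to the lower threshold; a degenerate
all-equal score set is flagged and assigned the grid midpoint). Boxes at
or above the threshold are the high-quality pseudo-labels used for
retraining; the threshold is re-selected every round from that round's
scores rather than frozen. The between-class-variance reading treats
pseudo-label quality as a two-class separation problem on the score
distribution; the per-threshold retained-count curve is logged alongside
for inspection, since score-only and count-aware readings are both
plausible. An empty filtered round halts the loop with a diagnostic
rather than training on nothing.

The mock detector emits jittered truth boxes near `score_high` plus
Poisson false boxes near `score_low`, and its training rule — each
self-training round multiplies the false-positive rate by 0.3 and lowers
the false-positive score mean by 0.1 — emulates a detector sharpening
under cleaner supervision. This makes the loop's central claim (retained
pseudo-label precision increases once the detector is retrained on
filtered labels) measurable without any neural component.

Evaluation uses greedy score-descending matching at IoU 0.5 (each truth
box matched at most once), the standard detection convention; the PR curve
sweeps the ranked predictions and AP integrates the precision envelope
over recall (all-points interpolation, not 11-point; with a single fruit
class mAP equals AP). Precision and recall are reported at the balance
point, the curve point minimizing |P - R| with ties toward higher recall.

## Numerical choices and degenerate inputs

* Seeds: every operation derives per-item streams from its seed with a
  Lehmer-style integer fold kept below 2^31, so collections are
  order-independent and fully reproducible.
* Rasters are quantized to the 8-bit grid at generation time, so
  in-memory arrays equal their PNG round trips bit for bit.
* Zero-variance descriptor sequences, empty foregrounds, all-identical
  scores, degenerate superellipse exponents, all-sky backgrounds, and
  sub-4-pixel jittered footprints all have defined, tested behavior
  (documented conventions or named errors) rather than NaN propagation.
* MDS configurations with fewer than two positive eigenvalues are
  zero-padded with a warning; rank-0 PCA blocks yield a zero axis with a
  warning.

## Problem sizes used by the test suite

The suite runs the scene-synthesis checks on 100 scenes of 10-30 fruits
(about 2,000 annotated instances), the source-recovery check on 20 seeded
runs of the 60-sprite planted collection, descriptor invariances on 20
sprites times 17 transforms, and the threshold/evaluator oracles on
50-instance randomized families — sizes chosen so the whole suite
exercises every claim at full fidelity while remaining comfortable to run
on a laptop.

## Known limitations

* The fused feature space keeps one principal axis per block; genuinely
  3-D-or-higher phenotype configurations can collapse (see above).
* Background segmentation is a fixed HSV/position heuristic intended for
  the generator's band-structured backgrounds and similar photographs; it
  is not a learned segmenter.
* The mock detector's training dynamics are a stylized stand-in; the
  self-learning loop's real-world behavior depends on the plugged-in
  detector.
* Occlusion bookkeeping counts only same-scene sprites composited later;
  it does not model translucency or soft shadows.
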