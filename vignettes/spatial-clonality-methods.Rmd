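---
title: "Methods: spatial clonality analysis for multicolor fate mapping"
author: "spatialClonality authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial clonality analysis for multicolor fate mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialClonality)
```

## The question the pipeline answers

Stochastic multicolor reporters (Confetti/Brainbow-type) permanently label
each recombined cell with one of a small set of fluorescent proteins —
here nGFP, cRFP, cYFP and mCFP — so that color marks clonal origin. If
labeled progenitors differentiate and expand *locally*, their descendants
form monochrome patches; if cells migrate and mix before settling, colors
interleave. The package turns tissue-section images of such reporters into
marked spatial point patterns and asks, per sample and then across a
cohort of samples: **are same-colored cells more spatially aggregated than
complete spatial randomness (CSR) would produce?**

Two complementary statistics address this:

1. **Mingling index (MI).** For each point, the fraction of its $k$
   nearest neighbours (default $k = 4$) carrying a *different* color;
   averaged over all points of the tissue. MI $= 0$ means every
   neighbourhood is exclusively one color; MI $= 1$ means neighbourhoods
   are entirely mixed. Local clonal expansion pushes MI *below* its CSR
   null.
2. **Voronoi cells-per-cluster.** The domain is tessellated by
   nearest-point allocation, adjacent tiles of the same color are merged
   into clusters, and the statistic is (number of tiles) / (number of
   clusters). Clonal patches push it *above* its CSR null.

A cohort is called *clustered* only when both statistics agree, each at
the configured significance level.

## Data model

- `MarkedPointPattern`: point locations in micrometres with one
  categorical color mark per point, plus a convex `DomainPolygon`
  boundary. The boundary is computed programmatically as the convex hull
  of all points of all colors (`computeLnBoundary()`), mirroring how a
  lymph-node outline is obtained from the overlay of the four reporters.
- Images are dense multichannel arrays (`ChannelImage`, one channel per
  reporter). `extractPointPattern()` thresholds each channel (Otsu by
  default — deterministic and parameter-free; a manual threshold can be
  recorded instead) and emits either one point per positive pixel
  (`mode = "pixel"`, the whole-section regime where patterns reach
  $10^5$–$10^6$ points) or one point per connected component
  (`mode = "centroid"`, for sparse cell-level data). Pixels positive in
  more than one channel are resolved by channel intensity (`argmax`),
  since the reporters are nominally mutually exclusive and co-positivity
  is treated as bleed-through; an `exclude` policy is available.
- Pixel convention: 0-based indices, $x$ = column, $y$ = row, and a pixel
  centre sits at $(\mathrm{col} + 0.5, \mathrm{row} + 0.5) \cdot
  \text{pixelSize}$ plus the image origin. Making this explicit keeps the
  render → extract round trip exact to within one pixel.

## The randomized Poisson null

Observed statistics are never compared with an analytic expectation but
with a *paired* Monte-Carlo null: each sample's pattern is re-drawn as CSR
inside **its own boundary** with **its own per-color counts**
(`randomizePattern()`), the statistic is recomputed, and the per-sample
null value is the mean over `nNullIterations` $= 10$ re-draws. Fixing the
per-color counts ("binomial" CSR, by rejection sampling from the bounding
box) removes the count variability a homogeneous Poisson process would
add, so each sample is compared against a null that differs only in
spatial arrangement. Because the null shares the sample's boundary and
counts, edge effects and color imbalance cancel in the comparison — which
is also why the MI deliberately uses **no edge correction**.

A mark-permutation null (`randomizePattern(method = "permute")`) is
available as a sensitivity analysis: it conditions on the observed
positions and randomizes only the color assignment, separating "colors
are clustered" from "cells are clustered". The primary analysis uses the
fresh-CSR null.

Across a cohort of $n \ge 2$ samples the observed and null per-sample
values are compared with a two-sided paired $t$-test; the direction
(observed lower / higher) is reported alongside. For equal four-color CSR
the MI null concentrates near $1 - \sum_c p_c^2 = 0.75$; the finite-$n$
permutation expectation is
$1 - \sum_c n_c (n_c - 1) / (n (n - 1))$.

## The Voronoi branch

Whole-section pixel patterns are too large to tessellate, so the pattern
is first downsampled by `downsampleFactor` $= 1000$, **each color
separately** (retaining $\mathrm{round}(n_c / \text{factor})$ points,
half away from zero, and never dropping a represented color) so the
subsample preserves the observed color ratio. The downsampled pattern is
tessellated, tiles are clipped to the convex boundary so they cover the
whole section, and adjacent same-color tiles are merged. Adjacency
requires a shared edge of *positive length* after clipping — tiles
touching at a single vertex do not merge — which makes degenerate
co-circular configurations deterministic. Coincident points (possible on
pixel grids) are merged before tessellation, erroring if their colors
conflict.

Each of the 10 null iterations follows the same route: CSR re-draw of the
full pattern, downsample, tessellate, merge; per-iteration
cells-per-cluster values are averaged with means. Since a uniform
subsample of uniformly distributed points is itself uniform, drawing the
null directly at the post-downsampling counts is *distributionally
identical* to the full re-draw; `nullVoronoiEnsemble(exact = FALSE)`
exposes that shortcut (an exact identity, not an approximation — the test
suite checks the two paths agree statistically), and the large repeated-
experiment loops use it.

## The synthetic generator

`simulateCSRPattern()` provides the null world. The clustered alternative
(`simulateClusteredPattern()`) is a Thomas-type parent–daughter process:
progenitors are placed uniformly in the domain, each draws one color (by
default the four reporters at equal probability — real Confetti outcome
frequencies are unequal and unknown a priori, so `colorProbs` is a
parameter, not a claim), and emits Poisson(`daughtersMean`) daughters
displaced by an isotropic Gaussian with scale `dispersionSigma`.
Daughters landing outside the domain are re-drawn, not clipped or
discarded, so the expected total stays
$n_\text{prog} (1 + \bar{m})$ analytically. With `daughtersMean = 0` the
process reduces exactly to CSR with multinomial colors — a degenerate-
alternative identity the tests exploit.

The default study conditions used throughout the tests and the acceptance
script are: 15 LNs per cohort; 200 progenitors; `daughtersMean` $= 9$
(so $\approx 2000$ cells per LN); `dispersionSigma` $= 10\,\mu m$; a
$1000 \times 600\,\mu m$ elliptical domain (a 64-vertex inscribed
polygon). For the Voronoi branch each cohort is pushed through the real
imaging front-end (`expandToPixelPattern()`): rendering at
$1\,\mu m/\mathrm{px}$ with a 5-px cell radius ($\approx 10\,\mu m$ cell
bodies, typical of stromal cells imaged at 20×), thresholding, and
pixel-mode extraction yield $\approx 10^5$ pixel-points per LN, so the
1000-fold downsampling leaves $\approx 100$ tiles. Rendering inside these
repeated-experiment loops is noiseless (noise robustness of the front-end
is exercised separately in the imaging tests); the maps, counts and
boundaries still travel the ordinary threshold/extract path.

What the generator does **not** emulate: 3D structure (sections are
analyzed as 2D), optical blur and channel bleed-through beyond Gaussian
background noise, tandem/multiple recombination events, uneven reporter
frequencies (available but not defaulted), and spatially inhomogeneous
cell density (the null is homogeneous CSR). Passing tests therefore show
the *procedures* behave as specified under controlled conditions — they
do not certify performance on real sections with anisotropic density or
imaging artifacts.

## Numerical and design choices

- **kNN ties.** Exact distance ties at the $k$-th neighbour (measure zero
  for continuous data, common on pixel grids) resolve in the
  deterministic order of the kd-tree backend; re-runs are identical.
  Coincident points are valid zero-distance neighbours for MI.
- **Downsampling rounding.** Round half away from zero with a floor of
  one point per represented color, so rare reporters are never silently
  dropped from the subsample.
- **Tile clipping.** Tessellation is computed in the domain's bounding
  rectangle and clipped to the convex boundary; the tile areas must sum
  to the domain area within $10^{-6}$ relative (enforced by a validity
  check), and adjacency uses a positive-length threshold of
  $10^{-9}$ × the domain extent.
- **Seeding.** Every stochastic stage accepts a seed; cohort-level
  functions derive independent substreams from one master seed via
  `sample.int`, so end-to-end runs are reproducible bit-for-bit.
- **Two statistics, no multiplicity correction.** MI and cells-per-cluster
  are confirmatory probes of the same hypothesis with opposite expected
  directions; the verdict requires both, which is conservative in itself.
- **Number of MI null iterations.** The Voronoi branch's 10 iterations
  are mirrored for MI (configurable); averaging several nulls halves the
  pairing noise relative to a single randomization.
- **Test problem sizes.** The repeated-experiment checks use 100 cohorts
  for detection rates and 200 for type-I calibration at the study
  conditions above; structural invariants (tile partition, adjacency vs a
  brute-force bisector-interval oracle) run on 100 random instances of up
  to 50 points, where exhaustive geometry is cheap.

## Limitations

- The convex-hull boundary overestimates concave lymph-node outlines;
  tiles and nulls near concavities inherit that bias. A measured boundary
  polygon can be supplied instead wherever a domain is accepted.
- The homogeneous CSR null does not separate clonal aggregation from
  density gradients; an intensity-matched inhomogeneous null is a natural
  extension and deliberately out of scope.
- The paired $t$-test treats samples as exchangeable; mouse-level
  hierarchy (several LNs per animal) is not modeled.
- Area-fraction quantification (`areaFraction()`) assumes the tissue mask
  is given; no automatic tissue segmentation is attempted.
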