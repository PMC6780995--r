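# spatialClonality

Spatial clonality analysis for multicolor (Confetti/Brainbow) fate-mapping
images of tissue sections.

## The problem

Stochastic multicolor reporters permanently mark each recombined cell with
one of a few fluorescent proteins (nGFP, cRFP, cYFP, mCFP), so color traces
clonal origin. Whether labeled progenitors differentiate **locally**
(producing monochrome patches, e.g. in the stromal network of a lymph node)
or mix before settling is a spatial question: are same-colored cells more
aggregated than complete spatial randomness (CSR) would produce?

`spatialClonality` answers it with two statistics on marked point patterns
extracted from multichannel images, each compared per sample against a
paired randomized Poisson null and then across samples with a paired
*t*-test:

- **Mingling index (MI)** — for each point, the fraction of its *k* = 4
  nearest neighbours carrying a *different* color, averaged over the
  tissue:

  MI_i = (1/k) · |{ j ∈ kNN(i) : m_j ≠ m_i }|,  MI = mean_i MI_i

  MI = 0 is locally monochrome, MI = 1 entirely mixed; local clonal
  expansion pushes MI *below* its CSR null (≈ 1 − Σ_c p_c² = 0.75 for
  four equally frequent colors).

- **Voronoi cells-per-cluster** — the section is tessellated by
  nearest-cell allocation (tiles clipped to the convex tissue boundary),
  adjacent same-color tiles are merged, and the statistic is
  n_tiles / n_clusters. Clonal patches push it *above* its CSR null.
  Whole-section pixel patterns (10⁵–10⁶ points) are first downsampled
  1000-fold, each color separately so the color ratio is preserved.

The package also provides the imaging front-end (Otsu/manual thresholding,
pixel- or centroid-mode point extraction, convex-hull boundary detection,
thresholded area-fraction quantification for single-reporter sections) and
a synthetic generator (CSR and clustered parent–daughter patterns, plus a
multichannel image renderer) so the entire pipeline is testable without
microscopy data.

## Worked example

Simulate six lymph nodes in which ~2000 cells arise from 200 color-labeled
progenitors (Poisson(9) daughters each, 10 µm dispersion) inside a
1000 × 600 µm elliptical boundary, then run both statistics against their
paired nulls:

```r
library(spatialClonality)

domain <- makeEllipticalDomain(500, 300)            # semi-axes in um
cohort <- simulateLnCohort(6, domain, mode = "clustered",
                           nProgenitors = 200, daughtersMean = 9,
                           dispersionSigma = 10, seed = 1)
cohort[[1]]
#> MarkedPointPattern: 2032 points, 4 color levels
#>   counts: nGFP=448, cRFP=624, cYFP=532, mCFP=428
#>   domain: 64-vertex convex polygon, area 4.705e+05 um^2

report <- analyzeCohort(cohort, analysisConfig(downsampleFactor = 10, seed = 2))
report
#> ClonalityReport: 6 samples, alpha = 0.05, verdict: clustered
#>   MI        : PairedComparison: n = 6, mean diff = -0.5308, t = -57.389, p = 3.04e-08 (observed_lower)
#>   cells/clu : PairedComparison: n = 6, mean diff = 1.526, t = 8.745, p = 0.000324 (observed_higher)

head(report@table, 3)
#>   sample_id mi_observed mi_null cells_per_cluster_observed cells_per_cluster_null
#> 1       LN1      0.1770  0.7471                     4.2292                 2.3036
#> 2       LN2      0.2049  0.7481                     4.3778                 2.3205
#> 3       LN3      0.2255  0.7497                     3.9800                 2.3212
```

Each LN's observed MI (~0.2) sits far below its randomized-Poisson null
(~0.75): neighbourhoods are much less mixed than chance, i.e. cells sit in
monochrome clonal patches. The Voronoi statistic agrees from the opposite
direction — same-color tiles merge into clusters of ~4 cells versus ~2.3
under the null — so the cohort verdict is "clustered". For real data,
replace the simulated cohort with patterns from
`extractPointPattern(readChannelImageTIFF("section.tif"))` or pattern CSVs
(`x_um,y_um,color`); `cmdSimulate()`/`cmdAnalyze()` and the
`inst/scripts/clonality-pipeline.R` wrapper drive the same path from the
shell.

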