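#' Simulate a cohort of synthetic lymph nodes
#'
#' Generates `nSamples` independent marked point patterns in the same
#' domain, either under the clustered clonal-expansion alternative or under
#' CSR with per-color counts matched to the clustered expectation
#' (`nProgenitors * (1 + daughtersMean) * colorProbs`), so the two modes
#' are directly comparable.
#'
#' @param nSamples number of LNs.
#' @param domain a [DomainPolygon-class] shared by all samples.
#' @param mode `"clustered"` or `"csr"`.
#' @param nProgenitors,daughtersMean,dispersionSigma,colorProbs clustered
#'   generator settings, see [clonalSimConfig()].
#' @param seed master seed; each sample gets its own derived substream.
#' @return list of [MarkedPointPattern-class] objects.
#' @export
simulateLnCohort <- function(nSamples, domain, mode = c("clustered", "csr"),
                             nProgenitors = 200L, daughtersMean = 9,
                             dispersionSigma = 10, colorProbs = NULL,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(colorProbs))
    colorProbs <- c(nGFP = 0.25, cRFP = 0.25, cYFP = 0.25, mCFP = 0.25)
  seeds <- .deriveSeeds(seed, nSamples)
  lapply(seq_len(nSamples), function(i) {
    if (mode == "clustered") {
      simulateClusteredPattern(clonalSimConfig(
        nProgenitors, colorProbs, daughtersMean, dispersionSigma,
        domain = domain, seed = seeds[i]))
    } else {
      counts <- round(nProgenitors * (1 + daughtersMean) * colorProbs)
      simulateCSRPattern(domain, counts, seed = seeds[i])
    }
  })
}

#' Push a cell-level pattern through the imaging front-end (pixel regime)
#'
#' Renders a pattern into a multichannel image and extracts it back in
#' pixel mode, so each cell becomes a disc of above-threshold pixels and
#' each positive pixel one point - the whole-LN analysis regime, where a
#' section yields on the order of 10^5 points. The returned pattern carries
#' the convex hull of all extracted points as its boundary.
#'
#' @param pattern a cell-level [MarkedPointPattern-class].
#' @param pixelSize micrometres per pixel (default 1).
#' @param spotRadius rendered cell radius in pixels (default 4, i.e. a
#'   ~9 um cell body at the default pixel size).
#' @param backgroundNoiseSd Gaussian noise added at rendering (default 0).
#' @param seed optional integer seed (noise only).
#' @return A pixel-level [MarkedPointPattern-class].
#' @export
expandToPixelPattern <- function(pattern, pixelSize = 1, spotRadius = 4L,
                                 backgroundNoiseSd = 0, seed = NULL) {
  img <- renderPatternToImage(pattern, pixelSize = pixelSize,
                              spotRadius = spotRadius,
                              backgroundNoiseSd = backgroundNoiseSd,
                              seed = seed)
  extractPointPattern(img, mode = "pixel", multiPositive = "argmax",
                      method = if (backgroundNoiseSd > 0) "otsu" else "manual",
                      manualValue = if (backgroundNoiseSd > 0) NULL else 0.5)
}

#' Run the full clonality analysis over a cohort of patterns
#'
#' For each sample: the pattern-level MI with its randomized-CSR null
#' ensemble, and/or the Voronoi cells-per-cluster statistic (after
#' ratio-preserving downsampling) with its null ensemble; then the paired
#' observed-vs-null tests across samples and the clustered/not-clustered
#' verdict.
#'
#' The Voronoi branch can be run in the pixel regime
#' (`pixelRegime = TRUE`): each pattern is first pushed through
#' [expandToPixelPattern()] so that the configured 1000-fold downsampling
#' acts on a pixel-level pattern, as in whole-LN image analysis. The MI
#' branch always runs on the patterns as given.
#'
#' @param patterns list of [MarkedPointPattern-class] objects with domains.
#' @param config an [AnalysisConfig-class]; its seed drives all null
#'   randomizations via derived substreams.
#' @param statistics subset of `c("mi", "voronoi")`.
#' @param pixelRegime expand patterns for the Voronoi branch (see above).
#' @param pixelSize,spotRadius pixel-regime settings.
#' @param fastNull use the direct (distributionally identical) draw of the
#'   downsampled Voronoi null instead of the literal full-size re-draw;
#'   see [nullVoronoiEnsemble()].
#' @param sampleIds sample identifiers (default LN1, LN2, ...).
#' @return A [ClonalityReport-class].
#' @export
analyzeCohort <- function(patterns, config = analysisConfig(),
                          statistics = c("mi", "voronoi"),
                          pixelRegime = FALSE, pixelSize = 1,
                          spotRadius = 4L, fastNull = FALSE,
                          sampleIds = NULL) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  nS <- length(patterns)
  if (is.null(sampleIds)) sampleIds <- paste0("LN", seq_len(nS))
  seeds <- .deriveSeeds(config@seed, 3L * nS)
  miObs <- miNul <- voObs <- voNul <- NULL
  if ("mi" %in% statistics) {
    miObs <- vector("list", nS); miNul <- vector("list", nS)
  }
  if ("voronoi" %in% statistics) {
    voObs <- vector("list", nS); voNul <- vector("list", nS)
  }
  for (i in seq_len(nS)) {
    p <- patterns[[i]]
    if (is.null(domain(p))) domain(p) <- computeLnBoundary(p)
    if ("mi" %in% statistics) {
      miObs[[i]] <- perPointMingling(p, k = config@kNeighbors)
      cfgI <- config; cfgI@seed <- seeds[3L * i - 2L]
      miNul[[i]] <- nullMinglingEnsemble(p, cfgI)
    }
    if ("voronoi" %in% statistics) {
      vp <- if (pixelRegime)
        expandToPixelPattern(p, pixelSize = pixelSize, spotRadius = spotRadius)
      else p
      down <- downsamplePattern(vp, config@downsampleFactor,
                                seed = seeds[3L * i - 1L])
      voObs[[i]] <- mergeSameColorClusters(
        buildVoronoi(down, boundary = domain(vp), computeTiles = FALSE))
      cfgI <- config; cfgI@seed <- seeds[3L * i]
      voNul[[i]] <- nullVoronoiEnsemble(vp, cfgI, exact = !fastNull)
    }
  }
  clusteringReport(sampleIds, miObserved = miObs, miNull = miNul,
                   voronoiObserved = voObs, voronoiNull = voNul,
                   alpha = config@alpha)
}
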