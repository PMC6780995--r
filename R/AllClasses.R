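# S4 class definitions for the spatial clonality pipeline.
#
# Coordinates are micrometres throughout; images use 0-based pixel indices
# with x = column and y = row, and a point sits at the pixel centre
# ((col + 0.5) * pixelSize, (row + 0.5) * pixelSize) plus the image origin.

#' DomainPolygon: convex tissue boundary
#'
#' A simple convex polygon (vertices in counter-clockwise order, micrometre
#' coordinates) representing the lymph-node boundary. All points of a
#' [MarkedPointPattern-class] live inside it, null patterns are generated
#' within it, and Voronoi tiles are clipped to it.
#'
#' @slot vertices numeric matrix (n x 2), counter-clockwise, n >= 3.
#' @slot area polygon area in square micrometres (shoelace formula).
#' @seealso [domainPolygon()], [makeEllipticalDomain()], [computeLnBoundary()]
#' @export
setClass("DomainPolygon",
  representation(vertices = "matrix", area = "numeric"))

setValidity("DomainPolygon", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L) return("vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 3L) return("a domain polygon needs at least 3 vertices")
  if (!all(is.finite(v))) return("vertices must be finite")
  a <- .polySignedArea(v)
  if (a <= 0) return("vertices must be in counter-clockwise order with positive area")
  if (!.isConvexCCW(v)) return("domain polygon must be convex")
  if (abs(object@area - a) > 1e-9 * max(1, a)) return("stored area does not match vertices")
  TRUE
})

setClassUnion("DomainPolygonOrNULL", c("DomainPolygon", "NULL"))

#' MarkedPointPattern: points with a categorical color mark
#'
#' The central data object of the analysis: 2D point locations (micrometres)
#' with one categorical color mark per point (e.g. the four Confetti
#' reporters nGFP, cRFP, cYFP, mCFP) and an optional convex domain boundary.
#' The full color set is carried as factor levels even when some colors have
#' zero points.
#'
#' @slot coords numeric matrix (n x 2), columns x and y in micrometres.
#' @slot marks factor of length n; levels are the color set.
#' @slot domain a [DomainPolygon-class] or `NULL` if no boundary is attached.
#' @seealso [markedPointPattern()], [simulateCSRPattern()],
#'   [extractPointPattern()]
#' @export
setClass("MarkedPointPattern",
  representation(coords = "matrix", marks = "factor",
                 domain = "DomainPolygonOrNULL"))

setValidity("MarkedPointPattern", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2L) return("coords must be an n x 2 matrix")
  if (length(object@marks) != n) return("one mark per point required")
  if (n > 0 && !all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(levels(object@marks)) < 1L) return("color level set must be non-empty")
  if (anyNA(object@marks)) return("marks must not contain NA")
  if (!is.null(object@domain) && n > 0) {
    inside <- .pointsInConvexPolygon(object@coords, vertices(object@domain))
    if (!all(inside)) {
      return(sprintf("%d point(s) fall outside the domain polygon", sum(!inside)))
    }
  }
  TRUE
})

#' MinglingResult: per-point and pattern-level mingling index
#'
#' The mingling index of a point is the fraction of its k nearest neighbours
#' carrying a different color mark; the pattern-level MI is the unweighted
#' mean over all points. MI = 0 means every neighbourhood is exclusively one
#' color, MI = 1 means every neighbourhood is entirely mixed.
#'
#' @slot perPoint numeric vector in \[0, 1\]; each value is a multiple of 1/k.
#' @slot meanMI arithmetic mean of `perPoint`.
#' @slot k number of nearest neighbours used (default 4 in the pipeline).
#' @seealso [perPointMingling()]
#' @export
setClass("MinglingResult",
  representation(perPoint = "numeric", meanMI = "numeric", k = "integer"))

setValidity("MinglingResult", function(object) {
  p <- object@perPoint
  if (object@k < 1L) return("k must be >= 1")
  if (length(p) == 0L) return("perPoint must be non-empty")
  if (any(p < -1e-12 | p > 1 + 1e-12)) return("per-point mingling must lie in [0, 1]")
  if (any(abs(p * object@k - round(p * object@k)) > 1e-9))
    return("per-point mingling must be a multiple of 1/k")
  if (abs(object@meanMI - mean(p)) > 1e-9) return("meanMI must equal mean(perPoint)")
  TRUE
})

#' BinaryMask: thresholded channel
#'
#' @slot pixels logical matrix (rows = image rows, cols = image columns).
#' @slot pixelSize micrometres per pixel.
#' @slot threshold the intensity threshold that produced the mask (provenance).
#' @slot method `"otsu"`, `"manual"`, or `""` for masks not born from
#'   thresholding.
#' @seealso [thresholdChannel()], [areaFraction()]
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", pixelSize = "numeric",
                 threshold = "numeric", method = "character"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("pixelSize must be a single positive number")
  TRUE
})

#' ChannelImage: multichannel fluorescence image
#'
#' A dense intensity array with one named channel per color reporter.
#' Storage order is `[row, column, channel]`; channel order is fixed by the
#' `channels` slot and preserved on disk (one TIFF frame per channel, in
#' order).
#'
#' @slot data numeric array, dim = c(nrow, ncol, nchannel).
#' @slot channels character vector naming the channels.
#' @slot pixelSize micrometres per pixel.
#' @slot origin (x, y) of the image's lower-left corner in micrometres, so
#'   pixel (row r, col c) (0-based) is centred at
#'   origin + ((c + 0.5), (r + 0.5)) * pixelSize.
#' @seealso [renderPatternToImage()], [extractPointPattern()]
#' @export
setClass("ChannelImage",
  representation(data = "array", channels = "character",
                 pixelSize = "numeric", origin = "numeric"))

setValidity("ChannelImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array [row, col, channel]")
  if (d[3L] != length(object@channels)) return("one channel name per data slice required")
  if (anyDuplicated(object@channels)) return("channel names must be unique")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (length(object@origin) != 2L) return("origin must be length 2")
  TRUE
})

#' AreaFractionResult: thresholded-signal area fraction
#'
#' Proportion of the tissue (lymph node) mask that is signal-positive,
#' mirroring a Fiji-style "Area Fraction" measurement on a thresholded
#' channel.
#'
#' @slot lnAreaPx number of pixels in the LN mask.
#' @slot positiveAreaPx number of signal-positive pixels inside the LN mask.
#' @slot fraction `positiveAreaPx / lnAreaPx`, in \[0, 1\].
#' @seealso [areaFraction()]
#' @export
setClass("AreaFractionResult",
  representation(lnAreaPx = "integer", positiveAreaPx = "integer",
                 fraction = "numeric"))

setValidity("AreaFractionResult", function(object) {
  if (object@lnAreaPx < 1L) return("LN mask must contain at least one pixel")
  if (object@positiveAreaPx > object@lnAreaPx)
    return("positive area cannot exceed LN area")
  if (abs(object@fraction - object@positiveAreaPx / object@lnAreaPx) > 1e-12)
    return("fraction must equal positiveAreaPx / lnAreaPx")
  TRUE
})

#' VoronoiTessellation: domain-clipped Voronoi tiles and their adjacency
#'
#' One tile per (distinct) point, clipped to the convex domain so the tiles
#' tessellate the whole LN area. Two tiles are adjacent iff they share a
#' boundary segment of positive length after clipping (single shared
#' vertices do not count).
#'
#' @slot sites numeric matrix of the (deduplicated) generating points.
#' @slot siteMarks factor, color mark per site.
#' @slot adjacency integer matrix (m x 2) of adjacent site index pairs, i < j.
#' @slot tiles list of tile polygons (n x 2 matrices, counter-clockwise),
#'   empty when tile geometry was not requested.
#' @slot tileAreas tile areas; empty when tile geometry was not requested.
#' @slot domain the clipping boundary.
#' @slot tilesComputed whether tile polygons/areas are present.
#' @seealso [buildVoronoi()], [mergeSameColorClusters()]
#' @export
setClass("VoronoiTessellation",
  representation(sites = "matrix", siteMarks = "factor", adjacency = "matrix",
                 tiles = "list", tileAreas = "numeric",
                 domain = "DomainPolygon", tilesComputed = "logical"))

setValidity("VoronoiTessellation", function(object) {
  n <- nrow(object@sites)
  if (length(object@siteMarks) != n) return("one mark per site required")
  if (ncol(object@adjacency) != 2L) return("adjacency must have two columns")
  if (nrow(object@adjacency) > 0) {
    a <- object@adjacency
    if (any(a[, 1L] >= a[, 2L])) return("adjacency pairs must satisfy i < j")
    if (any(a < 1L | a > n)) return("adjacency indices out of range")
  }
  if (object@tilesComputed) {
    if (length(object@tiles) != n || length(object@tileAreas) != n)
      return("tiles/areas must have one entry per site")
    rel <- abs(sum(object@tileAreas) - domainArea(object@domain)) /
      domainArea(object@domain)
    if (rel > 1e-6) return("tile areas must sum to the domain area (1e-6 relative)")
  }
  TRUE
})

#' VoronoiClusterResult: merged same-color cluster statistic
#'
#' Result of combining adjacent same-color Voronoi tiles into clusters. The
#' cells-per-cluster statistic is the number of original tiles divided by
#' the number of merged clusters; values near 1 indicate well-mixed colors,
#' larger values indicate clonal patches.
#'
#' @slot nTiles number of Voronoi tiles (distinct points).
#' @slot nClusters number of merged same-color clusters.
#' @slot cellsPerCluster `nTiles / nClusters`, >= 1.
#' @slot clusterSizes tiles per cluster; sums to `nTiles`.
#' @slot membership cluster id per tile.
#' @seealso [mergeSameColorClusters()]
#' @export
setClass("VoronoiClusterResult",
  representation(nTiles = "integer", nClusters = "integer",
                 cellsPerCluster = "numeric", clusterSizes = "integer",
                 membership = "integer"))

setValidity("VoronoiClusterResult", function(object) {
  if (object@nClusters > object@nTiles) return("cannot have more clusters than tiles")
  if (sum(object@clusterSizes) != object@nTiles)
    return("cluster sizes must sum to the tile count")
  if (abs(object@cellsPerCluster - object@nTiles / object@nClusters) > 1e-12)
    return("cellsPerCluster must equal nTiles / nClusters")
  if (length(object@membership) != object@nTiles)
    return("one cluster id per tile required")
  TRUE
})

#' NullEnsemble: statistics over randomized Poisson re-generations
#'
#' Holds the per-iteration values of a statistic (pattern-level MI or
#' cells-per-cluster) computed on randomized complete-spatial-randomness
#' re-draws of an observed pattern, plus their mean, which is the per-sample
#' null value used in paired observed-vs-null inference.
#'
#' @slot statisticName `"mean_mi"` or `"cells_per_cluster"`.
#' @slot values one value per null iteration.
#' @slot summary arithmetic mean of `values`.
#' @seealso [nullMinglingEnsemble()], [nullVoronoiEnsemble()]
#' @export
setClass("NullEnsemble",
  representation(statisticName = "character", values = "numeric",
                 summary = "numeric"))

setValidity("NullEnsemble", function(object) {
  if (!object@statisticName %in% c("mean_mi", "cells_per_cluster"))
    return("unknown statistic name")
  if (length(object@values) < 1L) return("at least one iteration required")
  if (abs(object@summary - mean(object@values)) > 1e-9)
    return("summary must be the mean of the iteration values")
  TRUE
})

#' PairedComparison: paired t-test of observed vs null statistics
#'
#' @slot observed per-sample observed statistic values.
#' @slot null per-sample null summaries (paired with `observed`).
#' @slot meanDifference mean of observed - null.
#' @slot tStatistic paired t statistic.
#' @slot pValue two-sided p-value.
#' @slot direction `"observed_lower"`, `"observed_higher"`, or `"none"`.
#' @seealso [pairedObservedVsNull()]
#' @export
setClass("PairedComparison",
  representation(observed = "numeric", null = "numeric",
                 meanDifference = "numeric", tStatistic = "numeric",
                 pValue = "numeric", direction = "character"))

setValidity("PairedComparison", function(object) {
  if (length(object@observed) != length(object@null))
    return("observed and null must be paired (equal length)")
  if (length(object@observed) < 2L) return("need at least two samples")
  if (object@pValue < 0 || object@pValue > 1) return("p-value out of range")
  if (!object@direction %in% c("observed_lower", "observed_higher", "none"))
    return("unknown direction")
  TRUE
})

#' AnalysisConfig: tunable parameters of the clonality analysis
#'
#' @slot kNeighbors neighbours used by the mingling index (default 4).
#' @slot nNullIterationsMi randomized null iterations for MI (default 10).
#' @slot nNullIterationsVoronoi null iterations for the Voronoi statistic
#'   (default 10).
#' @slot downsampleFactor ratio-preserving downsampling factor applied before
#'   Voronoi tessellation (default 1000).
#' @slot alpha significance level for paired tests (default 0.05).
#' @slot seed master seed; every stochastic stage derives its own substream
#'   from it. `NA` leaves the RNG state untouched.
#' @seealso [analysisConfig()]
#' @export
setClass("AnalysisConfig",
  representation(kNeighbors = "integer", nNullIterationsMi = "integer",
                 nNullIterationsVoronoi = "integer",
                 downsampleFactor = "numeric", alpha = "numeric",
                 seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  if (object@kNeighbors < 1L) return("kNeighbors must be >= 1")
  if (object@nNullIterationsMi < 1L || object@nNullIterationsVoronoi < 1L)
    return("null iteration counts must be >= 1")
  if (object@downsampleFactor < 1) return("downsampleFactor must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0, 1)")
  TRUE
})

#' ClonalSimConfig: clustered clonal-expansion generator settings
#'
#' Parameters of the parent-daughter (Thomas-type) process used as the
#' clustered alternative to complete spatial randomness: progenitors placed
#' uniformly in the domain each draw one color and emit a Poisson number of
#' daughters displaced by an isotropic Gaussian.
#'
#' @slot nProgenitors number of progenitor (parent) points.
#' @slot colorProbs named per-color probabilities, summing to 1.
#' @slot daughtersMean expected daughters per progenitor (>= 0).
#' @slot dispersionSigma daughter displacement scale in micrometres (>= 0).
#' @slot domain the tissue boundary.
#' @slot seed RNG seed (`NA` = leave RNG state untouched).
#' @seealso [clonalSimConfig()], [simulateClusteredPattern()]
#' @export
setClass("ClonalSimConfig",
  representation(nProgenitors = "integer", colorProbs = "numeric",
                 daughtersMean = "numeric", dispersionSigma = "numeric",
                 domain = "DomainPolygon", seed = "integer"))

setValidity("ClonalSimConfig", function(object) {
  if (object@nProgenitors < 1L) return("need at least one progenitor")
  p <- object@colorProbs
  if (is.null(names(p)) || anyDuplicated(names(p)) || length(p) < 1L)
    return("colorProbs must be a uniquely named vector")
  if (any(p < 0)) return("color probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) return("color probabilities must sum to 1 (tolerance 1e-9)")
  if (object@daughtersMean < 0) return("daughtersMean must be >= 0")
  if (object@dispersionSigma < 0) return("dispersionSigma must be >= 0")
  TRUE
})

setClassUnion("PairedComparisonOrNULL", c("PairedComparison", "NULL"))

#' ClonalityReport: per-sample table plus paired observed-vs-null tests
#'
#' @slot table data.frame with one row per sample (LN): observed and null MI,
#'   observed and null cells-per-cluster.
#' @slot miComparison paired test on MI (observed vs null), or NULL if fewer
#'   than two samples or MI was not computed.
#' @slot voronoiComparison paired test on cells-per-cluster, likewise.
#' @slot alpha significance level used for the verdict.
#' @slot verdict `"clustered"` when MI is significantly below its null and
#'   cells-per-cluster significantly above its null; else `"not clustered"`.
#' @seealso [clusteringReport()]
#' @export
setClass("ClonalityReport",
  representation(table = "data.frame",
                 miComparison = "PairedComparisonOrNULL",
                 voronoiComparison = "PairedComparisonOrNULL",
                 alpha = "numeric", verdict = "character"))
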