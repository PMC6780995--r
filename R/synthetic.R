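#' Simulate complete spatial randomness (CSR) with fixed per-color counts
#'
#' Places exactly the requested number of points of each color independently
#' and uniformly inside the domain (rejection sampling from the bounding
#' box). Fixing the per-color counts ("binomial" CSR) makes null patterns
#' exactly paired to an observed pattern: same counts, same boundary, only
#' the positions re-drawn.
#'
#' @param domain a [DomainPolygon-class].
#' @param countsPerColor named integer vector (or named list) giving the
#'   number of points of each color; names define the color level set.
#' @param seed optional integer seed (`NULL`/`NA` = use current RNG state).
#' @return A [MarkedPointPattern-class] with `sum(countsPerColor)` points.
#' @examples
#' d <- makeEllipticalDomain(500, 300)
#' p <- simulateCSRPattern(d, c(nGFP = 100, cRFP = 100), seed = 1)
#' markCounts(p)
#' @export
simulateCSRPattern <- function(domain, countsPerColor, seed = NULL) {
  if (!is(domain, "DomainPolygon")) stop("invalid domain")
  counts <- unlist(countsPerColor)
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("countsPerColor must be uniquely named")
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0L) stop("empty pattern: all per-color counts are zero")
  .maybeSetSeed(seed)
  pts <- .sampleUniformInPolygon(total, vertices(domain))
  marks <- rep(names(counts), times = counts)
  markedPointPattern(pts, marks, domain = domain,
                     colorLevels = names(counts))
}

#' Configuration for the clustered clonal-expansion generator
#'
#' @param nProgenitors number of progenitor (parent) cells.
#' @param colorProbs named numeric vector of per-color probabilities summing
#'   to 1; default is the four Confetti reporters at equal probability.
#' @param daughtersMean expected number of daughters per progenitor
#'   (Poisson mean, >= 0).
#' @param dispersionSigma isotropic Gaussian displacement scale of daughters
#'   around their progenitor, in micrometres.
#' @param domain a [DomainPolygon-class].
#' @param seed optional integer seed.
#' @return A [ClonalSimConfig-class].
#' @export
clonalSimConfig <- function(nProgenitors, colorProbs = NULL,
                            daughtersMean = 0, dispersionSigma = 0,
                            domain, seed = NA) {
  if (is.null(colorProbs))
    colorProbs <- c(nGFP = 0.25, cRFP = 0.25, cYFP = 0.25, mCFP = 0.25)
  if (!is(domain, "DomainPolygon")) stop("config error: invalid domain")
  cfg <- new("ClonalSimConfig", nProgenitors = as.integer(nProgenitors),
             colorProbs = colorProbs, daughtersMean = as.numeric(daughtersMean),
             dispersionSigma = as.numeric(dispersionSigma), domain = domain,
             seed = as.integer(if (is.null(seed)) NA else seed))
  cfg
}

#' Simulate a clustered clonal point pattern (parent-daughter process)
#'
#' The clustered alternative to CSR: `nProgenitors` parents are placed
#' uniformly in the domain; each parent draws one color from `colorProbs`
#' and emits a Poisson(`daughtersMean`) number of daughters displaced from
#' the parent by an isotropic Gaussian with standard deviation
#' `dispersionSigma` per axis. Daughters falling outside the domain are
#' re-drawn (not clipped or discarded) so the expected total point count
#' stays `nProgenitors * (1 + daughtersMean)`. Every daughter inherits its
#' parent's color, so small `dispersionSigma` produces tight monochrome
#' clones. With `daughtersMean = 0` the process reduces to CSR with
#' multinomial color counts.
#'
#' @param config a [ClonalSimConfig-class].
#' @return A [MarkedPointPattern-class]; parents first, then daughters
#'   grouped by parent. The generating parent index of each point is
#'   attached as attribute `"cloneId"`.
#' @examples
#' d <- makeEllipticalDomain(500, 300)
#' cfg <- clonalSimConfig(50, daughtersMean = 9, dispersionSigma = 10,
#'                        domain = d, seed = 7)
#' p <- simulateClusteredPattern(cfg)
#' @export
simulateClusteredPattern <- function(config) {
  if (!is(config, "ClonalSimConfig")) stop("config error: not a ClonalSimConfig")
  validObject(config)
  .maybeSetSeed(config@seed)
  v <- vertices(config@domain)
  np <- config@nProgenitors
  parents <- .sampleUniformInPolygon(np, v)
  cols <- names(config@colorProbs)
  parentColor <- sample(cols, np, replace = TRUE, prob = config@colorProbs)
  nd <- stats::rpois(np, config@daughtersMean)
  total <- sum(nd)
  if (total > 0) {
    parentIdx <- rep(seq_len(np), times = nd)
    dx <- stats::rnorm(total, sd = config@dispersionSigma)
    dy <- stats::rnorm(total, sd = config@dispersionSigma)
    pts <- cbind(parents[parentIdx, 1L] + dx, parents[parentIdx, 2L] + dy)
    # resample out-of-domain daughters until all are inside
    bad <- which(!.pointsInConvexPolygon(pts, v, tol = 0))
    guard <- 0L
    while (length(bad) > 0L) {
      pts[bad, 1L] <- parents[parentIdx[bad], 1L] +
        stats::rnorm(length(bad), sd = config@dispersionSigma)
      pts[bad, 2L] <- parents[parentIdx[bad], 2L] +
        stats::rnorm(length(bad), sd = config@dispersionSigma)
      bad <- bad[!.pointsInConvexPolygon(pts[bad, , drop = FALSE], v, tol = 0)]
      guard <- guard + 1L
      if (guard > 100000L)
        stop("config error: daughter resampling failed; dispersionSigma too large for the domain?")
    }
    allPts <- rbind(parents, pts)
    allMarks <- c(parentColor, parentColor[parentIdx])
    cloneId <- c(seq_len(np), parentIdx)
  } else {
    allPts <- parents
    allMarks <- parentColor
    cloneId <- seq_len(np)
  }
  out <- markedPointPattern(allPts, allMarks, domain = config@domain,
                            colorLevels = cols)
  attr(out, "cloneId") <- cloneId
  out
}

#' Render a point pattern into a noisy multichannel image
#'
#' Draws each point as a filled disc of saturating intensity (1.0) in the
#' channel of its color, on a pixel grid covering the domain bounding box
#' (or, without a domain, the point bounding box), then adds i.i.d. Gaussian
#' background noise per channel and clamps to `[0, 1]`. Channel order is the
#' color level order of the pattern and is preserved in the `channels` slot
#' and on disk.
#'
#' @param pattern a [MarkedPointPattern-class].
#' @param pixelSize micrometres per pixel (> 0).
#' @param spotRadius disc radius in pixels; 0 paints the single containing
#'   pixel.
#' @param backgroundNoiseSd standard deviation of the additive Gaussian
#'   noise (intensity units; 0 = noiseless).
#' @param seed optional integer seed for the noise.
#' @return A [ChannelImage-class].
#' @export
renderPatternToImage <- function(pattern, pixelSize, spotRadius = 2L,
                                 backgroundNoiseSd = 0, seed = NULL) {
  stopifnot(is(pattern, "MarkedPointPattern"))
  if (!is.finite(pixelSize) || pixelSize <= 0) stop("pixelSize must be positive")
  if (nPoints(pattern) == 0L) warning("empty pattern: rendering a noise-only image")
  if (is.null(domain(pattern)) && nPoints(pattern) == 0L)
    stop("cannot size an image for an empty pattern without a domain")
  box <- if (!is.null(domain(pattern))) vertices(domain(pattern)) else coords(pattern)
  origin <- c(min(box[, 1L]), min(box[, 2L]))
  w <- max(box[, 1L]) - origin[1L]
  h <- max(box[, 2L]) - origin[2L]
  ncol <- max(1L, ceiling(w / pixelSize) + 2L * spotRadius)
  nrow <- max(1L, ceiling(h / pixelSize) + 2L * spotRadius)
  origin <- origin - spotRadius * pixelSize  # margin so edge discs fit
  chans <- colorLevels(pattern)
  img <- array(0, dim = c(nrow, ncol, length(chans)))
  if (nPoints(pattern) > 0L) {
    xy <- coords(pattern)
    colIdx <- floor((xy[, 1L] - origin[1L]) / pixelSize)  # 0-based
    rowIdx <- floor((xy[, 2L] - origin[2L]) / pixelSize)
    # disc offsets
    r <- as.integer(spotRadius)
    off <- expand.grid(dr = -r:r, dc = -r:r)
    off <- off[off$dr^2 + off$dc^2 <= r^2 + 1e-9, , drop = FALSE]
    mk <- as.integer(marks(pattern))
    for (ch in seq_along(chans)) {
      sel <- which(mk == ch)
      if (length(sel) == 0L) next
      rows <- rep(rowIdx[sel], each = nrow(off)) + off$dr
      colsI <- rep(colIdx[sel], each = nrow(off)) + off$dc
      ok <- rows >= 0L & rows < nrow & colsI >= 0L & colsI < ncol
      img[cbind(rows[ok] + 1L, colsI[ok] + 1L, ch)] <- 1
    }
  }
  if (backgroundNoiseSd > 0) {
    .maybeSetSeed(seed)
    img <- img + stats::rnorm(length(img), sd = backgroundNoiseSd)
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  new("ChannelImage", data = img, channels = chans, pixelSize = pixelSize,
      origin = origin)
}

#' @rdname accessors
#' @export
setMethod("channelNames", "ChannelImage", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ChannelImage", function(x) x@pixelSize)

#' Extract one channel of a ChannelImage as an intensity matrix
#'
#' @param image a [ChannelImage-class].
#' @param channel channel name or index.
#' @return numeric matrix (rows x cols).
#' @export
getChannel <- function(image, channel) {
  stopifnot(is(image, "ChannelImage"))
  if (is.character(channel)) channel <- match(channel, image@channels)
  if (is.na(channel)) stop("config error: unknown channel")
  image@data[, , channel]
}

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("ChannelImage: %d x %d px, %d channel(s) [%s], %.3g um/px\n",
              d[1L], d[2L], d[3L], paste(object@channels, collapse = ", "),
              object@pixelSize))
})
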