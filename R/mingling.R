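#' Analysis configuration
#'
#' Bundles the tunable parameters of the clonality analysis. By default the
#' mingling index uses the four nearest neighbours, both null ensembles use
#' 10 randomized iterations, and the Voronoi stage downsamples the point
#' pattern 1000-fold (the whole-section pixel regime).
#'
#' @param kNeighbors nearest neighbours for the mingling index.
#' @param nNullIterationsMi randomized null iterations for MI.
#' @param nNullIterationsVoronoi randomized null iterations for the Voronoi
#'   statistic.
#' @param downsampleFactor ratio-preserving downsampling factor before
#'   tessellation.
#' @param alpha significance level for paired tests.
#' @param seed master seed (`NA` = use the current RNG state).
#' @return An [AnalysisConfig-class].
#' @export
analysisConfig <- function(kNeighbors = 4L, nNullIterationsMi = 10L,
                           nNullIterationsVoronoi = 10L,
                           downsampleFactor = 1000, alpha = 0.05,
                           seed = NA) {
  new("AnalysisConfig", kNeighbors = as.integer(kNeighbors),
      nNullIterationsMi = as.integer(nNullIterationsMi),
      nNullIterationsVoronoi = as.integer(nNullIterationsVoronoi),
      downsampleFactor = as.numeric(downsampleFactor),
      alpha = as.numeric(alpha),
      seed = as.integer(if (is.null(seed)) NA else seed))
}

# k-nearest-neighbour index matrix (n x k), self excluded; duplicates are
# valid neighbours at distance 0. kd-tree order is deterministic; exact
# distance ties at the k-th neighbour resolve in tree order.
.knnIndices <- function(xy, k) {
  n <- nrow(xy)
  if (n < k + 1L) stop("insufficient points: need at least k + 1")
  idx <- RANN::nn2(xy, xy, k = k + 1L)$nn.idx
  keep <- idx != seq_len(n)
  # with coincident points the query itself may be absent from the k+1
  # returned; then drop the farthest instead
  extra <- rowSums(keep) == k + 1L
  keep[extra, k + 1L] <- FALSE
  matrix(t(idx)[t(keep)], ncol = k, byrow = TRUE)
}

#' Per-point and pattern-level mingling index
#'
#' For each point, the mingling index is the fraction of its `k` nearest
#' neighbours (Euclidean distance, self excluded) whose color mark differs
#' from the point's own; the pattern-level MI is the unweighted mean over
#' all points. A neighbourhood that is exclusively one color scores 0; an
#' entirely mixed neighbourhood scores 1. No edge correction is applied:
#' boundary points use their ordinary nearest neighbours, and the paired
#' CSR null (same counts, same boundary) absorbs edge effects.
#'
#' @param pattern a [MarkedPointPattern-class] with at least `k + 1` points.
#' @param k number of neighbours (default 4).
#' @return A [MinglingResult-class].
#' @examples
#' p <- markedPointPattern(cbind(0:4, 0), c("A", "B", "A", "B", "A"))
#' meanMI(perPointMingling(p, 4))  # 0.6
#' @export
perPointMingling <- function(pattern, k = 4L) {
  stopifnot(is(pattern, "MarkedPointPattern"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nPoints(pattern) < k + 1L)
    stop("insufficient points: mingling with k = ", k, " needs at least ",
         k + 1L, " points")
  nn <- .knnIndices(coords(pattern), k)
  mk <- as.integer(marks(pattern))
  diffs <- matrix(mk[nn], ncol = k) != mk
  per <- rowMeans(diffs)
  new("MinglingResult", perPoint = per, meanMI = mean(per), k = k)
}

#' @rdname accessors
#' @export
setMethod("perPointMI", "MinglingResult", function(x) x@perPoint)

#' @rdname accessors
#' @export
setMethod("meanMI", "MinglingResult", function(x) x@meanMI)

setMethod("show", "MinglingResult", function(object) {
  cat(sprintf("MinglingResult: %d points, k = %d, mean MI = %.4f\n",
              length(object@perPoint), object@k, object@meanMI))
})

#' Smoothed per-color probability maps
#'
#' Converts a marked point pattern into per-color probability surfaces: a
#' Gaussian-kernel intensity estimate per color on a regular grid, with the
#' per-color values normalized to sum to 1 at every grid cell inside the
#' domain. Cells with (numerically) zero total intensity, or outside the
#' domain, are `NA`. These maps are a visualization of local lineage
#' composition, not an inferential statistic.
#'
#' @param pattern a [MarkedPointPattern-class] with a domain.
#' @param bandwidth Gaussian kernel standard deviation in micrometres;
#'   default is twice the mean nearest-neighbour distance of the pattern.
#' @param gridSpacing grid cell size in micrometres; default divides the
#'   longer domain side into 128 cells.
#' @return list with elements `x`, `y` (grid cell-centre coordinates),
#'   `probability` (named list of matrices, one per color, rows = y),
#'   and `bandwidth`.
#' @export
colorProbabilityMap <- function(pattern, bandwidth = NULL,
                                gridSpacing = NULL) {
  stopifnot(is(pattern, "MarkedPointPattern"))
  if (is.null(domain(pattern))) stop("pattern needs a domain")
  if (nPoints(pattern) == 0L) stop("undefined map: pattern has no points")
  xy <- coords(pattern)
  v <- vertices(domain(pattern))
  if (is.null(bandwidth)) {
    nnd <- RANN::nn2(xy, xy, k = min(2L, nrow(xy)))$nn.dists
    bandwidth <- if (ncol(nnd) >= 2L) 2 * mean(nnd[, 2L]) else
      diff(range(v[, 1L])) / 10
    if (bandwidth <= 0) bandwidth <- diff(range(v[, 1L])) / 10
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  if (is.null(gridSpacing)) gridSpacing <- max(diff(xr), diff(yr)) / 128
  gx <- seq(xr[1L] + gridSpacing / 2, xr[2L], by = gridSpacing)
  gy <- seq(yr[1L] + gridSpacing / 2, yr[2L], by = gridSpacing)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  insideG <- .pointsInConvexPolygon(grid, v)
  lv <- colorLevels(pattern)
  mk <- marks(pattern)
  dens <- matrix(0, nrow(grid), length(lv))
  inv2s2 <- 1 / (2 * bandwidth^2)
  for (ci in seq_along(lv)) {
    pts <- xy[mk == lv[ci], , drop = FALSE]
    if (nrow(pts) == 0L) next
    # kernel sums in chunks to bound memory
    acc <- numeric(nrow(grid))
    step <- max(1L, floor(5e6 / nrow(grid)))
    for (s in seq(1L, nrow(pts), by = step)) {
      e <- min(nrow(pts), s + step - 1L)
      d2 <- outer(grid[, 1L], pts[s:e, 1L], "-")^2 +
            outer(grid[, 2L], pts[s:e, 2L], "-")^2
      acc <- acc + rowSums(exp(-d2 * inv2s2))
    }
    dens[, ci] <- acc
  }
  tot <- rowSums(dens)
  defined <- insideG & tot > .Machine$double.xmin
  prob <- dens / ifelse(tot > 0, tot, 1)
  prob[!defined, ] <- NA_real_
  maps <- lapply(seq_along(lv), function(ci)
    matrix(prob[, ci], nrow = length(gy), ncol = length(gx), byrow = TRUE))
  names(maps) <- lv
  list(x = gx, y = gy, probability = maps, bandwidth = bandwidth)
}
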