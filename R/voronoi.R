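#' Ratio-preserving downsampling of a point pattern
#'
#' Downsamples each color separately so the color ratio of the subsample
#' matches the full pattern: a color with `n_c` points retains
#' `round(n_c / factor)` points (round half away from zero, minimum 1 for
#' any color that is present), chosen uniformly without replacement. Used
#' before Voronoi tessellation for computational practicality; whole-section
#' pixel-level patterns typically use `factor = 1000`.
#'
#' @param pattern a non-empty [MarkedPointPattern-class].
#' @param factor downsampling factor (>= 1).
#' @param seed optional integer seed.
#' @return A [MarkedPointPattern-class] with the same domain and color
#'   levels.
#' @examples
#' d <- makeEllipticalDomain(100, 100)
#' p <- simulateCSRPattern(d, c(A = 4000, B = 2000, C = 1000, D = 1000),
#'                         seed = 1)
#' markCounts(downsamplePattern(p, 1000))  # 4, 2, 1, 1
#' @export
downsamplePattern <- function(pattern, factor, seed = NULL) {
  stopifnot(is(pattern, "MarkedPointPattern"))
  if (!is.finite(factor) || factor < 1) stop("invalid parameter: factor must be >= 1")
  if (nPoints(pattern) == 0L) stop("empty pattern")
  if (factor == 1) return(pattern)
  .maybeSetSeed(seed)
  mk <- marks(pattern)
  keep <- integer(0)
  for (lv in levels(mk)) {
    idx <- which(mk == lv)
    nc <- length(idx)
    if (nc == 0L) next
    m <- max(1L, as.integer(floor(nc / factor + 0.5)))  # round half away from zero
    keep <- c(keep, if (m >= nc) idx else idx[sample.int(nc, m)])
  }
  pattern[sort(keep)]
}

#' Voronoi tessellation clipped to a convex boundary
#'
#' Tessellates the domain by nearest-point allocation: each (distinct)
#' point's Voronoi cell is intersected with the convex boundary so the
#' tiles jointly cover the whole LN area. Two tiles are adjacent iff their
#' shared Voronoi edge has positive length after clipping; tiles meeting
#' only at a vertex are not adjacent. Coincident duplicate points are
#' merged with a warning when their colors agree and are an error
#' otherwise.
#'
#' The Delaunay/Voronoi computation itself is delegated to
#' \pkg{deldir}; clipping to the convex boundary and the adjacency rule are
#' applied on top.
#'
#' @param pattern a [MarkedPointPattern-class] with >= 2 distinct points.
#' @param boundary clipping boundary; defaults to the pattern's domain.
#' @param computeTiles compute tile polygons and areas (needed for
#'   geometry; the cluster statistic only needs adjacency, so ensemble
#'   loops can skip this).
#' @return A [VoronoiTessellation-class].
#' @examples
#' sq <- domainPolygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' p <- markedPointPattern(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)) * 0.98 + 0.01,
#'                         c("A", "A", "B", "B"), sq)
#' tess <- buildVoronoi(p, sq)
#' tileAreas(tess)  # four quadrants of ~0.25
#' @export
buildVoronoi <- function(pattern, boundary = NULL, computeTiles = TRUE) {
  stopifnot(is(pattern, "MarkedPointPattern"))
  if (is.null(boundary)) boundary <- domain(pattern)
  if (is.null(boundary)) stop("invalid input: no boundary available")
  xy <- coords(pattern)
  mk <- marks(pattern)
  key <- paste(xy[, 1L], xy[, 2L])
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    grp <- match(key, key[first])
    agree <- tapply(as.integer(mk), grp, function(z) length(unique(z)) == 1L)
    if (!all(agree))
      stop("duplicate conflict: coincident points with different colors")
    warning(sprintf("merged %d duplicate point(s) before tessellation",
                    sum(!first)))
    xy <- xy[first, , drop = FALSE]
    mk <- mk[first]
  }
  n <- nrow(xy)
  if (n < 2L) stop("degenerate tessellation: need at least 2 distinct points")
  v <- vertices(boundary)
  rw <- c(range(v[, 1L]), range(v[, 2L]))
  dd <- deldir::deldir(xy[, 1L], xy[, 2L], rw = rw, suppressMsge = TRUE)
  # adjacency: Voronoi segments with positive length inside the boundary
  sg <- dd$dirsgs
  lens <- .clipSegmentsToConvex(sg$x1, sg$y1, sg$x2, sg$y2, v)
  scale <- max(rw[2L] - rw[1L], rw[4L] - rw[3L])
  pos <- lens > 1e-9 * scale
  a <- cbind(pmin(sg$ind1, sg$ind2), pmax(sg$ind1, sg$ind2))[pos, , drop = FALSE]
  a <- unique(a)
  storage.mode(a) <- "integer"
  tilesL <- list(); areas <- numeric(0)
  if (computeTiles) {
    tl <- deldir::tile.list(dd)
    tilesL <- vector("list", n)
    areas <- numeric(n)
    inside <- .pointsInConvexPolygon(xy, v)
    for (i in seq_len(n)) {
      poly <- cbind(tl[[i]]$x, tl[[i]]$y)
      # clip only tiles that can poke outside the boundary
      if (all(.pointsInConvexPolygon(poly, v))) {
        clipped <- poly
      } else {
        clipped <- .clipPolygonToConvex(poly, v)
      }
      tilesL[[i]] <- clipped
      areas[i] <- if (nrow(clipped) >= 3L) .polySignedArea(.ensureCCW(clipped)) else 0
    }
  }
  new("VoronoiTessellation", sites = xy, siteMarks = mk, adjacency = a,
      tiles = tilesL, tileAreas = areas, domain = boundary,
      tilesComputed = computeTiles)
}

#' @rdname accessors
#' @export
setMethod("nTiles", "VoronoiTessellation", function(x) nrow(x@sites))

#' @rdname accessors
#' @export
setMethod("tiles", "VoronoiTessellation", function(x) {
  if (!x@tilesComputed) stop("tiles were not computed; rebuild with computeTiles = TRUE")
  x@tiles
})

#' @rdname accessors
#' @export
setMethod("tileAreas", "VoronoiTessellation", function(x) {
  if (!x@tilesComputed) stop("tile areas were not computed; rebuild with computeTiles = TRUE")
  x@tileAreas
})

#' @rdname accessors
#' @export
setMethod("adjacencyEdges", "VoronoiTessellation", function(x) x@adjacency)

#' @rdname accessors
#' @export
setMethod("marks", "VoronoiTessellation", function(x) x@siteMarks)

#' @rdname accessors
#' @export
setMethod("domain", "VoronoiTessellation", function(x) x@domain)

setMethod("show", "VoronoiTessellation", function(object) {
  cat(sprintf("VoronoiTessellation: %d tiles, %d adjacent pairs%s\n",
              nTiles(object), nrow(object@adjacency),
              if (object@tilesComputed) "" else " (adjacency only)"))
})

#' Merge adjacent same-color Voronoi tiles into clusters
#'
#' Clusters are the connected components of the tile adjacency graph
#' restricted to each color; the cells-per-cluster statistic divides the
#' number of original tiles by the number of merged clusters. A monochrome
#' tessellation of a convex domain merges to a single cluster
#' (cells-per-cluster = number of tiles); a tessellation in which no two
#' adjacent tiles share a color yields one cluster per tile
#' (cells-per-cluster = 1).
#'
#' @param tess a [VoronoiTessellation-class].
#' @param marks color mark per tile; defaults to the marks carried by the
#'   tessellation.
#' @return A [VoronoiClusterResult-class].
#' @export
mergeSameColorClusters <- function(tess, marks = NULL) {
  stopifnot(is(tess, "VoronoiTessellation"))
  if (is.null(marks)) marks <- tess@siteMarks
  n <- nTiles(tess)
  if (length(marks) != n) stop("need one mark per tile")
  mk <- as.integer(factor(as.character(marks)))
  a <- tess@adjacency
  same <- a[mk[a[, 1L]] == mk[a[, 2L]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(same, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership)
  sizes <- as.integer(tabulate(membership))
  new("VoronoiClusterResult", nTiles = as.integer(n),
      nClusters = as.integer(comp$no),
      cellsPerCluster = n / comp$no,
      clusterSizes = sizes, membership = membership)
}

#' @rdname accessors
#' @export
setMethod("nClusters", "VoronoiClusterResult", function(x) x@nClusters)

#' @rdname accessors
#' @export
setMethod("cellsPerCluster", "VoronoiClusterResult", function(x) x@cellsPerCluster)

#' @rdname accessors
#' @export
setMethod("clusterSizes", "VoronoiClusterResult", function(x) x@clusterSizes)

#' @rdname accessors
#' @export
setMethod("nTiles", "VoronoiClusterResult", function(x) x@nTiles)

setMethod("show", "VoronoiClusterResult", function(object) {
  cat(sprintf("VoronoiClusterResult: %d tiles -> %d clusters, cells/cluster = %.3f\n",
              object@nTiles, object@nClusters, object@cellsPerCluster))
})
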