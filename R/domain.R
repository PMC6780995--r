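#' Construct a convex domain polygon
#'
#' Builds the convex tissue boundary used to contain point patterns, generate
#' nulls, and clip Voronoi tiles. Vertices are reordered counter-clockwise if
#' supplied clockwise; non-convex input is an error.
#'
#' @param vertices numeric matrix or data.frame with two columns (x, y in
#'   micrometres), at least three rows.
#' @return A [DomainPolygon-class].
#' @examples
#' sq <- domainPolygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' domainArea(sq)
#' @export
domainPolygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 3L)
    stop("invalid domain: need an n x 2 numeric matrix with n >= 3")
  if (!all(is.finite(v))) stop("invalid domain: vertices must be finite")
  dimnames(v) <- NULL
  v <- .ensureCCW(v)
  a <- .polySignedArea(v)
  if (a <= 0) stop("invalid domain: polygon has no area")
  if (!.isConvexCCW(v)) stop("invalid domain: polygon is not convex")
  new("DomainPolygon", vertices = v, area = a)
}

#' Convex polygon inscribed in an ellipse
#'
#' Convenience stand-in for a lymph-node outline: a regular polygon inscribed
#' in the axis-aligned ellipse with the given semi-axes, centred at the
#' origin. Its area is \eqn{(n/2) \sin(2\pi/n) \, a b}, converging to
#' \eqn{\pi a b} as the vertex count grows.
#'
#' @param semiAxisA,semiAxisB semi-axes in micrometres (> 0).
#' @param nVertices number of vertices (>= 8 for a reasonable outline;
#'   >= 3 accepted).
#' @return A [DomainPolygon-class].
#' @examples
#' d <- makeEllipticalDomain(500, 300, 64)
#' domainArea(d) / (pi * 500 * 300)  # ~0.998
#' @export
makeEllipticalDomain <- function(semiAxisA, semiAxisB, nVertices = 64L) {
  if (!is.finite(semiAxisA) || !is.finite(semiAxisB) ||
      semiAxisA <= 0 || semiAxisB <= 0)
    stop("invalid parameter: semi-axes must be positive")
  nVertices <- as.integer(nVertices)
  if (nVertices < 3L) stop("invalid parameter: need at least 3 vertices")
  th <- 2 * pi * (seq_len(nVertices) - 1L) / nVertices
  domainPolygon(cbind(semiAxisA * cos(th), semiAxisB * sin(th)))
}

#' @rdname accessors
#' @export
setMethod("vertices", "DomainPolygon", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("domainArea", "DomainPolygon", function(x) x@area)

setMethod("show", "DomainPolygon", function(object) {
  v <- object@vertices
  cat(sprintf("DomainPolygon: %d vertices, area %.4g um^2\n",
              nrow(v), object@area))
  cat(sprintf("  x range [%.4g, %.4g], y range [%.4g, %.4g] um\n",
              min(v[, 1L]), max(v[, 1L]), min(v[, 2L]), max(v[, 2L])))
})

#' Test whether points lie inside a domain polygon
#'
#' @param domain a [DomainPolygon-class].
#' @param pts n x 2 coordinate matrix.
#' @return logical vector; boundary points count as inside.
#' @export
insideDomain <- function(domain, pts) {
  stopifnot(is(domain, "DomainPolygon"))
  .pointsInConvexPolygon(as.matrix(pts), vertices(domain))
}
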