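# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (RANN, deldir) used by the package.

# k nearest neighbours by full distance matrix; ties broken by point index
bruteKnn <- function(xy, k) {
  n <- nrow(xy)
  res <- vapply(seq_len(n), function(i) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    d2[i] <- Inf
    order(d2, seq_len(n))[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

bruteMingling <- function(xy, marks, k) {
  nn <- bruteKnn(xy, k)
  vapply(seq_len(nrow(xy)), function(i) mean(marks[nn[i, ]] != marks[i]),
         numeric(1))
}

# Voronoi adjacency oracle: sites i and j share an edge of positive length
# inside the convex CCW polygon `dom` iff the bisector of (i, j), restricted
# to the half-planes of all other sites and of the domain, is a segment of
# positive length. Solved by interval intersection along the bisector line -
# an algorithm independent of the tessellation library.
bisectorAdjacencyOracle <- function(xy, dom, tol = 1e-9) {
  n <- nrow(xy)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi. <- xy[i, ]; pj <- xy[j, ]
    m <- (pi. + pj) / 2
    dir <- pj - pi.
    u <- c(-dir[2], dir[1])
    u <- u / sqrt(sum(u^2))
    lo <- -Inf; hi <- Inf
    ok <- TRUE
    # closer to i (and j) than to every other site k: linear constraint in t
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      pk <- xy[k, ]
      c0 <- 2 * sum(m * (pk - pi.)) + sum(pi.^2) - sum(pk^2)
      c1 <- 2 * sum(u * (pk - pi.))
      # need c0 + c1 t <= 0
      if (abs(c1) < 1e-14) { if (c0 > 0) { ok <- FALSE; break } }
      else if (c1 > 0) hi <- min(hi, -c0 / c1)
      else lo <- max(lo, -c0 / c1)
    }
    if (!ok) next
    nv <- nrow(dom)
    for (e in seq_len(nv)) {
      f <- if (e == nv) 1L else e + 1L
      ex <- dom[f, 1] - dom[e, 1]; ey <- dom[f, 2] - dom[e, 2]
      # inside: ex*(qy - ay) - ey*(qx - ax) >= 0, q = m + t u
      c0 <- ex * (m[2] - dom[e, 2]) - ey * (m[1] - dom[e, 1])
      c1 <- ex * u[2] - ey * u[1]
      if (abs(c1) < 1e-14) { if (c0 < 0) { ok <- FALSE; break } }
      else if (c1 > 0) lo <- max(lo, -c0 / c1)
      else hi <- min(hi, -c0 / c1)
    }
    if (ok && hi - lo > tol) edges <- rbind(edges, c(i, j))
  }
  edges
}

# connected components by union-find (independent of igraph)
unionFindComponents <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  if (!is.null(edges)) for (r in seq_len(nrow(edges))) {
    ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# shoelace area for test-side geometry
shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

unitSquareDomain <- function() domainPolygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))

# small clustered cohort settings reused across tests (kept modest so the
# default run stays fast)
testDomain <- function() makeEllipticalDomain(500, 300, 64)
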