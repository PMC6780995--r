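# Internal convex-polygon geometry. Everything assumes counter-clockwise
# (CCW) vertex order; constructors enforce it once so the hot paths don't.

# signed shoelace area; > 0 for CCW
.polySignedArea <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

.ensureCCW <- function(v) {
  if (.polySignedArea(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

# convexity of a CCW polygon: every consecutive cross product >= -tol.
# collinear vertices are tolerated (chull never emits them, but inscribed
# polygons built from rounded angles can come numerically close).
.isConvexCCW <- function(v, tol = NULL) {
  n <- nrow(v)
  ex <- c(v[-1L, 1L], v[1L, 1L]) - v[, 1L]
  ey <- c(v[-1L, 2L], v[1L, 2L]) - v[, 2L]
  cr <- ex * c(ey[-1L], ey[1L]) - ey * c(ex[-1L], ex[1L])
  if (is.null(tol)) tol <- 1e-9 * max(ex^2 + ey^2)
  all(cr >= -tol)
}

# vectorized point-in-convex-polygon (boundary counts as inside)
.pointsInConvexPolygon <- function(pts, v, tol = NULL) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  n <- nrow(v)
  if (is.null(tol)) {
    scale <- max(abs(range(v))) + 1
    tol <- 1e-9 * scale^2
  }
  inside <- rep(TRUE, nrow(pts))
  px <- pts[, 1L]; py <- pts[, 2L]
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # cross((v_j - v_i), (p - v_i)) >= 0 for CCW interior
    cr <- (v[j, 1L] - v[i, 1L]) * (py - v[i, 2L]) -
          (v[j, 2L] - v[i, 2L]) * (px - v[i, 1L])
    inside <- inside & (cr >= -tol)
    if (!any(inside)) break
  }
  inside
}

# Sutherland-Hodgman: clip an arbitrary simple polygon against a convex CCW
# polygon. Returns an m x 2 matrix (possibly 0 rows).
.clipPolygonToConvex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) break
    j <- if (i == nc) 1L else i + 1L
    ax <- clip[i, 1L]; ay <- clip[i, 2L]
    ex <- clip[j, 1L] - ax; ey <- clip[j, 2L] - ay
    px <- out[, 1L]; py <- out[, 2L]
    s <- ex * (py - ay) - ey * (px - ax)    # >= 0 is inside
    m <- nrow(out)
    nxt <- c(2:m, 1L)[seq_len(m)]
    if (m == 1L) nxt <- 1L
    sn <- s[nxt]
    keep_in <- s >= 0
    crossing <- xor(keep_in, sn >= 0)
    # intersection parameters for crossing edges
    t <- ifelse(crossing, s / (s - sn), NA_real_)
    ix <- px + t * (px[nxt] - px)
    iy <- py + t * (py[nxt] - py)
    newx <- newy <- numeric(0)
    for (vtx in seq_len(m)) {
      if (keep_in[vtx]) { newx <- c(newx, px[vtx]); newy <- c(newy, py[vtx]) }
      if (crossing[vtx]) { newx <- c(newx, ix[vtx]); newy <- c(newy, iy[vtx]) }
    }
    out <- cbind(newx, newy)
  }
  dimnames(out) <- NULL
  out
}

# Vectorized clipping of many segments against a convex CCW polygon
# (Liang-Barsky against each half-plane). Returns clipped lengths.
.clipSegmentsToConvex <- function(x1, y1, x2, y2, clip) {
  t0 <- rep(0, length(x1)); t1 <- rep(1, length(x1))
  dx <- x2 - x1; dy <- y2 - y1
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    j <- if (i == nc) 1L else i + 1L
    ex <- clip[j, 1L] - clip[i, 1L]; ey <- clip[j, 2L] - clip[i, 2L]
    # inside: ex*(y - ay) - ey*(x - ax) >= 0
    f1 <- ex * (y1 - clip[i, 2L]) - ey * (x1 - clip[i, 1L])
    fd <- ex * dy - ey * dx
    # param t where f = f1 + t*fd crosses 0
    ent <- fd > 0          # moving into the half-plane
    ext <- fd < 0
    tcross <- -f1 / fd
    t0 <- ifelse(ent, pmax(t0, tcross), t0)
    t1 <- ifelse(ext, pmin(t1, tcross), t1)
    par <- fd == 0 & f1 < 0  # parallel and fully outside
    t1 <- ifelse(par, -1, t1)
  }
  len <- sqrt(dx^2 + dy^2) * pmax(0, t1 - t0)
  len[!is.finite(len)] <- 0
  len
}

# uniform points in a convex polygon by rejection sampling from the
# bounding box; consumes the current RNG stream
.sampleUniformInPolygon <- function(n, v) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  accept_est <- max(0.1, .polySignedArea(v) / ((xr[2L] - xr[1L]) * (yr[2L] - yr[1L])))
  out <- matrix(numeric(0), ncol = 2L)
  guard <- 0L
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / accept_est) + 16L
    cand <- cbind(stats::runif(m, xr[1L], xr[2L]), stats::runif(m, yr[1L], yr[2L]))
    keep <- .pointsInConvexPolygon(cand, v, tol = 0)
    out <- rbind(out, cand[keep, , drop = FALSE])
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed to fill the domain")
  }
  out[seq_len(n), , drop = FALSE]
}

# derive independent integer sub-seeds from one master seed
.deriveSeeds <- function(seed, n) {
  if (is.null(seed) || is.na(seed)) return(rep(NA_integer_, n))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.maybeSetSeed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
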