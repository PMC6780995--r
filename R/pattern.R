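#' Construct a marked point pattern
#'
#' @param coords n x 2 matrix (or data.frame) of x, y positions in
#'   micrometres.
#' @param marks character or factor of length n with the color mark of each
#'   point.
#' @param domain optional [DomainPolygon-class] containing all points.
#' @param colorLevels optional character vector fixing the full color set
#'   (so colors with zero points are retained as factor levels).
#' @return A [MarkedPointPattern-class].
#' @examples
#' d <- domainPolygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' p <- markedPointPattern(cbind(c(.2, .8), c(.5, .5)), c("cRFP", "cYFP"), d)
#' nPoints(p)
#' @export
markedPointPattern <- function(coords, marks, domain = NULL,
                               colorLevels = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 2L)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (is.factor(marks) && is.null(colorLevels)) colorLevels <- levels(marks)
  if (is.null(colorLevels)) colorLevels <- sort(unique(as.character(marks)))
  marks <- factor(as.character(marks), levels = colorLevels)
  new("MarkedPointPattern", coords = coords, marks = marks, domain = domain)
}

#' @rdname accessors
#' @export
setMethod("coords", "MarkedPointPattern", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("marks", "MarkedPointPattern", function(x) x@marks)

#' @rdname accessors
#' @export
setMethod("nPoints", "MarkedPointPattern", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setMethod("colorLevels", "MarkedPointPattern", function(x) levels(x@marks))

#' @rdname accessors
#' @export
setMethod("markCounts", "MarkedPointPattern", function(x) table(x@marks))

#' @rdname accessors
#' @export
setMethod("domain", "MarkedPointPattern", function(x) x@domain)

#' @rdname accessors
#' @export
setMethod("domain<-", "MarkedPointPattern", function(x, value) {
  x@domain <- value
  validObject(x)
  x
})

#' @describeIn markedPointPattern subset a pattern by point index
#' @param x a [MarkedPointPattern-class].
#' @param i index vector.
#' @export
setMethod("[", "MarkedPointPattern", function(x, i) {
  markedPointPattern(x@coords[i, , drop = FALSE], x@marks[i],
                     domain = x@domain, colorLevels = levels(x@marks))
})

setMethod("show", "MarkedPointPattern", function(object) {
  cat(sprintf("MarkedPointPattern: %d points, %d color levels\n",
              nPoints(object), length(levels(object@marks))))
  tab <- table(object@marks)
  cat("  counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (is.null(object@domain)) {
    cat("  domain: none\n")
  } else {
    cat(sprintf("  domain: %d-vertex convex polygon, area %.4g um^2\n",
                nrow(vertices(object@domain)), domainArea(object@domain)))
  }
})
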