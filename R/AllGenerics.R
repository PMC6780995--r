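#' @include AllClasses.R
NULL

#' Accessors for spatialClonality objects
#'
#' Small generic accessor family used across the package instead of direct
#' slot access.
#'
#' @param x an object.
#' @param value replacement value.
#' @return The slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("marks", function(x) standardGeneric("marks"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("colorLevels", function(x) standardGeneric("colorLevels"))

#' @rdname accessors
#' @export
setGeneric("markCounts", function(x) standardGeneric("markCounts"))

#' @rdname accessors
#' @export
setGeneric("domain", function(x) standardGeneric("domain"))

#' @rdname accessors
#' @export
setGeneric("domain<-", function(x, value) standardGeneric("domain<-"))

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("domainArea", function(x) standardGeneric("domainArea"))

#' @rdname accessors
#' @export
setGeneric("perPointMI", function(x) standardGeneric("perPointMI"))

#' @rdname accessors
#' @export
setGeneric("meanMI", function(x) standardGeneric("meanMI"))

#' @rdname accessors
#' @export
setGeneric("nTiles", function(x) standardGeneric("nTiles"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("cellsPerCluster", function(x) standardGeneric("cellsPerCluster"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("tiles", function(x) standardGeneric("tiles"))

#' @rdname accessors
#' @export
setGeneric("tileAreas", function(x) standardGeneric("tileAreas"))

#' @rdname accessors
#' @export
setGeneric("adjacencyEdges", function(x) standardGeneric("adjacencyEdges"))

#' @rdname accessors
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname accessors
#' @export
setGeneric("nullSummary", function(x) standardGeneric("nullSummary"))

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
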