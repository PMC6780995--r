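#' Per-sample clonality report with paired observed-vs-null tests
#'
#' Assembles the across-sample (per-LN) comparison that decides whether a
#' tissue shows local clonal structure: one row per sample with observed
#' and null MI and observed and null cells-per-cluster, plus a paired
#' t-test per statistic. The verdict is `"clustered"` only when both
#' statistics agree at level `alpha`: MI significantly below its null
#' (neighbourhoods less mixed than random) and cells-per-cluster
#' significantly above its null (same-color tiles merge into larger
#' patches than random).
#'
#' @param sampleIds character vector of sample (LN) identifiers.
#' @param miObserved numeric vector or list of [MinglingResult-class], one
#'   per sample; `NULL` to skip the MI branch.
#' @param miNull numeric vector or list of [NullEnsemble-class], paired
#'   null summaries for MI.
#' @param voronoiObserved numeric vector or list of
#'   [VoronoiClusterResult-class]; `NULL` to skip the Voronoi branch.
#' @param voronoiNull numeric vector or list of [NullEnsemble-class].
#' @param alpha significance level (default 0.05). The two statistics are
#'   confirmatory of one hypothesis, so no multiplicity correction is
#'   applied across them.
#' @return A [ClonalityReport-class].
#' @export
clusteringReport <- function(sampleIds, miObserved = NULL, miNull = NULL,
                             voronoiObserved = NULL, voronoiNull = NULL,
                             alpha = 0.05) {
  nS <- length(sampleIds)
  if (nS < 2L) stop("input error: paired comparison needs at least 2 samples")
  asNum <- function(x, f) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) vapply(x, f, numeric(1)) else as.numeric(x)
  }
  miObs <- asNum(miObserved, function(o) meanMI(o))
  miNul <- asNum(miNull, function(o) nullSummary(o))
  voObs <- asNum(voronoiObserved, function(o) cellsPerCluster(o))
  voNul <- asNum(voronoiNull, function(o) nullSummary(o))
  for (v in list(miObs, miNul, voObs, voNul))
    if (!is.null(v) && length(v) != nS)
      stop("input error: per-sample vectors must match sampleIds in length")
  tab <- data.frame(sample_id = as.character(sampleIds))
  miCmp <- voCmp <- NULL
  if (!is.null(miObs)) {
    tab$mi_observed <- miObs
    tab$mi_null <- miNul
    miCmp <- pairedObservedVsNull(miObs, miNul)
  }
  if (!is.null(voObs)) {
    tab$cells_per_cluster_observed <- voObs
    tab$cells_per_cluster_null <- voNul
    voCmp <- pairedObservedVsNull(voObs, voNul)
  }
  clustered <- !is.null(miCmp) && !is.null(voCmp) &&
    miCmp@pValue < alpha && miCmp@direction == "observed_lower" &&
    voCmp@pValue < alpha && voCmp@direction == "observed_higher"
  # with only one branch available, that branch alone decides
  if (is.null(voCmp) && !is.null(miCmp))
    clustered <- miCmp@pValue < alpha && miCmp@direction == "observed_lower"
  if (is.null(miCmp) && !is.null(voCmp))
    clustered <- voCmp@pValue < alpha && voCmp@direction == "observed_higher"
  new("ClonalityReport", table = tab, miComparison = miCmp,
      voronoiComparison = voCmp, alpha = alpha,
      verdict = if (clustered) "clustered" else "not clustered")
}

setMethod("show", "ClonalityReport", function(object) {
  cat(sprintf("ClonalityReport: %d samples, alpha = %g, verdict: %s\n",
              nrow(object@table), object@alpha, object@verdict))
  if (!is.null(object@miComparison)) {
    cat("  MI        : "); show(object@miComparison)
  }
  if (!is.null(object@voronoiComparison)) {
    cat("  cells/clu : "); show(object@voronoiComparison)
  }
})
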