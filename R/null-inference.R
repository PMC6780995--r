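#' Randomized Poisson (CSR) re-draw of an observed pattern
#'
#' Generates the paired null for an observed pattern. The default
#' (`method = "csr"`) draws complete spatial randomness inside the observed
#' boundary with exactly the observed per-color counts: observed positions
#' are discarded, only counts and the boundary are kept. The alternative
#' (`method = "permute"`) keeps the observed positions and shuffles the
#' marks among them - a sensitivity analysis that conditions on the
#' observed spatial density and only randomizes the color assignment.
#'
#' @param pattern a non-empty [MarkedPointPattern-class] with a domain.
#' @param seed optional integer seed.
#' @param method `"csr"` (fresh positions) or `"permute"` (mark shuffle).
#' @return A [MarkedPointPattern-class].
#' @export
randomizePattern <- function(pattern, seed = NULL,
                             method = c("csr", "permute")) {
  stopifnot(is(pattern, "MarkedPointPattern"))
  method <- match.arg(method)
  if (is.null(domain(pattern))) stop("invalid input: pattern has no boundary")
  if (nPoints(pattern) == 0L) stop("invalid input: empty pattern")
  if (method == "permute") {
    .maybeSetSeed(seed)
    return(markedPointPattern(coords(pattern), sample(marks(pattern)),
                              domain = domain(pattern),
                              colorLevels = levels(marks(pattern))))
  }
  counts <- table(marks(pattern))
  simulateCSRPattern(domain(pattern),
                     stats::setNames(as.integer(counts), names(counts)),
                     seed = seed)
}

#' Null ensemble of the mingling index
#'
#' Computes the pattern-level MI on `nNullIterationsMi` randomized CSR
#' re-draws of the observed pattern; the ensemble summary (their mean) is
#' the per-sample null MI used in paired inference.
#'
#' @param pattern a [MarkedPointPattern-class] with a domain and at least
#'   `kNeighbors + 1` points.
#' @param config an [AnalysisConfig-class].
#' @param method null construction passed to [randomizePattern()]; the
#'   default fresh-CSR null is the primary analysis, `"permute"` is a
#'   sensitivity check.
#' @return A [NullEnsemble-class] with `statisticName = "mean_mi"`.
#' @export
nullMinglingEnsemble <- function(pattern, config = analysisConfig(),
                                 method = c("csr", "permute")) {
  stopifnot(is(pattern, "MarkedPointPattern"), is(config, "AnalysisConfig"))
  method <- match.arg(method)
  iters <- config@nNullIterationsMi
  seeds <- .deriveSeeds(config@seed, iters)
  vals <- vapply(seq_len(iters), function(i) {
    nul <- randomizePattern(pattern, seed = seeds[i], method = method)
    meanMI(perPointMingling(nul, k = config@kNeighbors))
  }, numeric(1))
  new("NullEnsemble", statisticName = "mean_mi", values = vals,
      summary = mean(vals))
}

#' Null ensemble of the Voronoi cells-per-cluster statistic
#'
#' Each iteration re-draws the observed pattern as CSR (same counts, same
#' boundary), applies the ratio-preserving downsampling, tessellates, and
#' merges same-color clusters; the per-iteration cells-per-cluster values
#' are averaged using means.
#'
#' Because uniform subsampling of uniformly distributed points is again
#' uniform, drawing the null directly at the post-downsampling per-color
#' counts (`exact = FALSE`) produces the identical distribution while
#' skipping the full-size re-draw; large ensemble loops use that path.
#'
#' @param pattern a non-empty [MarkedPointPattern-class] with a domain.
#' @param config an [AnalysisConfig-class].
#' @param exact if `TRUE` (default) follow the literal procedure
#'   (full-size CSR re-draw, then downsample); if `FALSE` draw the
#'   downsampled null directly.
#' @return A [NullEnsemble-class] with `statisticName = "cells_per_cluster"`.
#' @export
nullVoronoiEnsemble <- function(pattern, config = analysisConfig(),
                                exact = TRUE) {
  stopifnot(is(pattern, "MarkedPointPattern"), is(config, "AnalysisConfig"))
  if (is.null(domain(pattern))) stop("invalid input: pattern has no boundary")
  iters <- config@nNullIterationsVoronoi
  seeds <- .deriveSeeds(config@seed, iters)
  counts <- table(marks(pattern))
  downCounts <- ifelse(counts > 0,
                       pmax(1L, as.integer(floor(counts / config@downsampleFactor + 0.5))),
                       0L)
  if (sum(downCounts) < 2L)
    stop("insufficient points: downsampled pattern has fewer than 2 points")
  vals <- vapply(seq_len(iters), function(i) {
    if (exact) {
      nul <- randomizePattern(pattern, seed = seeds[i])
      nul <- downsamplePattern(nul, config@downsampleFactor)
    } else {
      nul <- simulateCSRPattern(domain(pattern),
                                stats::setNames(as.integer(downCounts), names(counts)),
                                seed = seeds[i])
    }
    tess <- buildVoronoi(nul, computeTiles = FALSE)
    cellsPerCluster(mergeSameColorClusters(tess))
  }, numeric(1))
  new("NullEnsemble", statisticName = "cells_per_cluster", values = vals,
      summary = mean(vals))
}

#' @rdname accessors
#' @export
setMethod("nullValues", "NullEnsemble", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("nullSummary", "NullEnsemble", function(x) x@summary)

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble[%s]: %d iterations, mean = %.4f (sd %.4f)\n",
              object@statisticName, length(object@values), object@summary,
              stats::sd(object@values)))
})

#' Paired observed-vs-null comparison
#'
#' Two-sided paired t-test on per-sample differences (observed - null),
#' with the direction of the effect reported from the sign of the mean
#' difference.
#'
#' @param observed per-sample observed statistic (one value per LN).
#' @param nullSummaries per-sample null summaries, paired with `observed`.
#' @return A [PairedComparison-class].
#' @examples
#' pairedObservedVsNull(c(0.60, 0.62, 0.58, 0.61),
#'                      c(0.75, 0.74, 0.76, 0.73))
#' @export
pairedObservedVsNull <- function(observed, nullSummaries) {
  if (length(observed) != length(nullSummaries))
    stop("input error: observed and null vectors differ in length")
  if (length(observed) < 2L)
    stop("input error: paired test needs at least 2 samples")
  d <- observed - nullSummaries
  if (stats::sd(d) == 0)
    stop("degenerate test: differences have zero variance")
  tt <- stats::t.test(observed, nullSummaries, paired = TRUE)
  md <- mean(d)
  new("PairedComparison", observed = as.numeric(observed),
      null = as.numeric(nullSummaries), meanDifference = md,
      tStatistic = unname(tt$statistic), pValue = tt$p.value,
      direction = if (md < 0) "observed_lower"
                  else if (md > 0) "observed_higher" else "none")
}

setMethod("show", "PairedComparison", function(object) {
  cat(sprintf("PairedComparison: n = %d, mean diff = %.4g, t = %.3f, p = %.3g (%s)\n",
              length(object@observed), object@meanDifference,
              object@tStatistic, object@pValue, object@direction))
})
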