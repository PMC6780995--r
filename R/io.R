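# Plain-text and TIFF serialization of the pipeline's objects.
#
# Pattern CSV dialect: header x_um,y_um,color, one point per row.
# Domain CSV dialect: header x_um,y_um, one vertex per row (CCW).

#' Read and write marked point patterns as CSV
#'
#' @param pattern a [MarkedPointPattern-class].
#' @param path CSV file path.
#' @param domain optional [DomainPolygon-class] to attach on read.
#' @param colorLevels optional color level set to impose on read.
#' @return `writePatternCSV` returns `path` invisibly; `readPatternCSV`
#'   returns a [MarkedPointPattern-class].
#' @export
writePatternCSV <- function(pattern, path) {
  stopifnot(is(pattern, "MarkedPointPattern"))
  df <- data.frame(x_um = coords(pattern)[, 1L], y_um = coords(pattern)[, 2L],
                   color = as.character(marks(pattern)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePatternCSV
#' @export
readPatternCSV <- function(path, domain = NULL, colorLevels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "color")
  if (!all(need %in% names(df)))
    stop("pattern CSV must have columns x_um, y_um, color")
  markedPointPattern(cbind(df$x_um, df$y_um), df$color, domain = domain,
                     colorLevels = colorLevels)
}

#' Read and write domain polygons as CSV vertex lists
#'
#' @param domain a [DomainPolygon-class].
#' @param path CSV file path (columns x_um, y_um).
#' @return `writeDomainCSV` returns `path` invisibly; `readDomainCSV`
#'   returns a [DomainPolygon-class].
#' @export
writeDomainCSV <- function(domain, path) {
  stopifnot(is(domain, "DomainPolygon"))
  v <- vertices(domain)
  utils::write.csv(data.frame(x_um = v[, 1L], y_um = v[, 2L]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDomainCSV
#' @export
readDomainCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("domain CSV must have columns x_um, y_um")
  domainPolygon(cbind(df$x_um, df$y_um))
}

#' Write a multichannel image as a multi-page TIFF
#'
#' One 32-bit float page per channel, in channel order. Channel names,
#' pixel size, and origin are written to a JSON sidecar
#' (`<path>.channels.json`), since baseline TIFF tags cannot carry them;
#' `readChannelImageTIFF` picks the sidecar up automatically when present.
#'
#' @param image a [ChannelImage-class].
#' @param path TIFF path.
#' @param mask a [BinaryMask-class] (written as 8-bit 0/255).
#' @return the path, invisibly.
#' @export
writeChannelImageTIFF <- function(image, path) {
  stopifnot(is(image, "ChannelImage"))
  pages <- lapply(seq_along(image@channels),
                  function(ch) image@data[, , ch])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(channels = image@channels,
                            pixel_size_um = image@pixelSize,
                            origin_um = image@origin),
                       paste0(path, ".channels.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeChannelImageTIFF
#' @param pixelSize,origin metadata to use when no sidecar is found.
#' @export
readChannelImageTIFF <- function(path, pixelSize = 1, origin = c(0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  chans <- paste0("ch", seq_along(pages))
  sidecar <- paste0(path, ".channels.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (length(meta$channels) == length(pages)) chans <- meta$channels
    if (!is.null(meta$pixel_size_um)) pixelSize <- meta$pixel_size_um
    if (!is.null(meta$origin_um)) origin <- meta$origin_um
  }
  arr <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  new("ChannelImage", data = arr, channels = chans, pixelSize = pixelSize,
      origin = origin)
}

#' @rdname writeChannelImageTIFF
#' @export
writeBinaryMaskTIFF <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  tiff::writeTIFF(maskPixels(mask) * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write per-color probability maps as a multi-page TIFF
#'
#' One 32-bit float page per color, in the map's color order; undefined
#' cells (outside the domain or with zero kernel mass) are stored as NaN.
#' Color names go to the same JSON sidecar convention as
#' [writeChannelImageTIFF()].
#'
#' @param map result of [colorProbabilityMap()].
#' @param path TIFF path.
#' @return the path, invisibly.
#' @export
writeProbabilityMapsTIFF <- function(map, path) {
  if (!is.list(map) || is.null(map$probability))
    stop("map must be the result of colorProbabilityMap()")
  pages <- lapply(map$probability, function(m) { m[is.na(m)] <- NaN; m })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(channels = names(map$probability),
                            bandwidth_um = map$bandwidth),
                       paste0(path, ".channels.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Append an area-fraction measurement to a results CSV
#'
#' Creates the file with a header on first use, then appends one row
#' (sample_id, ln_area_px, positive_area_px, fraction) per call.
#'
#' @param result an [AreaFractionResult-class].
#' @param sampleId sample identifier for the row.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
appendAreaFractionCSV <- function(result, sampleId, path) {
  stopifnot(is(result, "AreaFractionResult"))
  row <- data.frame(sample_id = as.character(sampleId),
                    ln_area_px = result@lnAreaPx,
                    positive_area_px = result@positiveAreaPx,
                    fraction = result@fraction)
  newFile <- !file.exists(path)
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = newFile, append = !newFile, quote = FALSE)
  invisible(path)
}

#' Serialize a mingling result
#'
#' Writes the per-point table (point index, x, y, color, mingling) as CSV
#' and, optionally, a JSON summary `{n, k, mean_mi}`.
#'
#' @param result a [MinglingResult-class].
#' @param pattern the pattern the result was computed on.
#' @param path CSV path.
#' @param jsonPath optional JSON summary path.
#' @return the CSV path, invisibly.
#' @export
writeMinglingCSV <- function(result, pattern, path, jsonPath = NULL) {
  stopifnot(is(result, "MinglingResult"), is(pattern, "MarkedPointPattern"))
  df <- data.frame(point = seq_len(nPoints(pattern)),
                   x_um = coords(pattern)[, 1L], y_um = coords(pattern)[, 2L],
                   color = as.character(marks(pattern)),
                   mingling = perPointMI(result))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(n = nPoints(pattern), k = result@k,
                              mean_mi = meanMI(result)),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Serialize a Voronoi cluster result as JSON
#'
#' @param result a [VoronoiClusterResult-class].
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
writeClusterJSON <- function(result, path) {
  stopifnot(is(result, "VoronoiClusterResult"))
  jsonlite::write_json(list(n_tiles = result@nTiles,
                            n_clusters = result@nClusters,
                            cells_per_cluster = result@cellsPerCluster,
                            cluster_sizes = result@clusterSizes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a clonality report as CSV plus JSON summary
#'
#' The CSV holds the per-sample table; the JSON carries the paired test
#' results, the verdict, and provenance (alpha, config echo if supplied).
#'
#' @param report a [ClonalityReport-class].
#' @param csvPath,jsonPath output paths.
#' @param config optional [AnalysisConfig-class] echoed into the JSON.
#' @return `csvPath`, invisibly.
#' @export
writeReport <- function(report, csvPath, jsonPath = NULL, config = NULL) {
  stopifnot(is(report, "ClonalityReport"))
  utils::write.csv(report@table, csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath)) {
    cmp <- function(x) if (is.null(x)) NULL else
      list(mean_difference = x@meanDifference, t = x@tStatistic,
           p_value = x@pValue, direction = x@direction)
    out <- list(n_samples = nrow(report@table), alpha = report@alpha,
                verdict = report@verdict, mi = cmp(report@miComparison),
                cells_per_cluster = cmp(report@voronoiComparison))
    if (!is.null(config)) {
      out$config <- list(k_neighbors = config@kNeighbors,
                         n_null_iterations_mi = config@nNullIterationsMi,
                         n_null_iterations_voronoi = config@nNullIterationsVoronoi,
                         downsample_factor = config@downsampleFactor,
                         alpha = config@alpha,
                         seed = if (is.na(config@seed)) NULL else config@seed)
    }
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(csvPath)
}
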