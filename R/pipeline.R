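# Orchestration entry points behind the command-line wrapper
# (inst/scripts/clonality-pipeline.R). Both functions are plain R and fully
# testable without a shell.

#' Simulate a cohort of LNs and write them to disk
#'
#' Writes one pattern CSV per replicate (plus optionally a rendered
#' multichannel TIFF), a shared domain CSV, and a manifest JSON listing
#' files, per-replicate seeds, and the generator mode.
#'
#' @param outdir output directory (created if missing).
#' @param replicates number of LNs to simulate.
#' @param mode `"clustered"` or `"csr"`; a clustered request with
#'   `daughtersMean = 0` is flagged as CSR-equivalent in the manifest.
#' @param domain a [DomainPolygon-class]; default 1000 x 600 um ellipse.
#' @param nProgenitors,daughtersMean,dispersionSigma,colorProbs generator
#'   settings, see [simulateLnCohort()].
#' @param renderImages also write rendered TIFFs (noise `imageNoiseSd`).
#' @param pixelSize,spotRadius,imageNoiseSd rendering settings.
#' @param seed master seed.
#' @return the manifest as a list, invisibly.
#' @export
cmdSimulate <- function(outdir, replicates = 15L,
                        mode = c("clustered", "csr"),
                        domain = NULL, nProgenitors = 200L,
                        daughtersMean = 9, dispersionSigma = 10,
                        colorProbs = NULL, renderImages = FALSE,
                        pixelSize = 1, spotRadius = 4L, imageNoiseSd = 0.05,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(domain)) domain <- makeEllipticalDomain(500, 300)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("I/O error: cannot create ", outdir)
  seeds <- .deriveSeeds(seed, replicates + 1L)
  effMode <- if (mode == "clustered" && daughtersMean == 0) "csr" else mode
  patterns <- simulateLnCohort(replicates, domain, mode = mode,
                               nProgenitors = nProgenitors,
                               daughtersMean = daughtersMean,
                               dispersionSigma = dispersionSigma,
                               colorProbs = colorProbs, seed = seeds[1L])
  domainFile <- file.path(outdir, "domain.csv")
  writeDomainCSV(domain, domainFile)
  entries <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    f <- file.path(outdir, sprintf("ln%03d.csv", i))
    writePatternCSV(patterns[[i]], f)
    entry <- list(pattern = basename(f), seed = seeds[i + 1L], mode = effMode)
    if (renderImages) {
      tf <- file.path(outdir, sprintf("ln%03d.tif", i))
      img <- renderPatternToImage(patterns[[i]], pixelSize = pixelSize,
                                  spotRadius = spotRadius,
                                  backgroundNoiseSd = imageNoiseSd,
                                  seed = seeds[i + 1L])
      writeChannelImageTIFF(img, tf)
      entry$image <- basename(tf)
    }
    entries[[i]] <- entry
  }
  manifest <- list(mode = effMode, replicates = replicates, seed = seed,
                   domain = basename(domainFile),
                   generator = list(n_progenitors = nProgenitors,
                                    daughters_mean = daughtersMean,
                                    dispersion_sigma = dispersionSigma),
                   samples = entries)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Analyze a set of pattern CSVs or multichannel TIFFs
#'
#' Runs the full clonality analysis (mingling index and Voronoi
#' cells-per-cluster, each against its randomized Poisson null) over all
#' inputs and writes `report.csv` and `report.json` into `outdir`. TIFF
#' inputs are first converted to point patterns via
#' [extractPointPattern()]; with a single input the per-sample statistics
#' are still computed and written, but the paired tests are skipped with a
#' warning.
#'
#' @param inputs character vector of pattern CSV paths and/or TIFF paths.
#' @param outdir output directory.
#' @param config an [AnalysisConfig-class].
#' @param channelMap named character vector mapping TIFF channel names to
#'   color marks (required for TIFF inputs whose pages carry no channel
#'   names).
#' @param mode point extraction mode for TIFFs, `"pixel"` or `"centroid"`.
#' @param pixelSize micrometres per pixel assumed for TIFF inputs.
#' @param domainFile optional domain CSV applied to all CSV patterns
#'   (otherwise each pattern's convex hull is used).
#' @param statistics subset of `c("mi", "voronoi")`.
#' @param fastNull see [analyzeCohort()].
#' @return A [ClonalityReport-class] (or per-sample list for a single
#'   input), invisibly.
#' @export
cmdAnalyze <- function(inputs, outdir, config = analysisConfig(),
                       channelMap = NULL, mode = "pixel", pixelSize = 1,
                       domainFile = NULL, statistics = c("mi", "voronoi"),
                       fastNull = FALSE) {
  if (length(inputs) < 1L) stop("config error: no inputs given")
  missingIn <- inputs[!file.exists(inputs)]
  if (length(missingIn))
    stop("config error: missing input(s): ", paste(missingIn, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dom <- if (!is.null(domainFile)) readDomainCSV(domainFile) else NULL
  isTiff <- grepl("\\.tiff?$", inputs, ignore.case = TRUE)
  patterns <- lapply(seq_along(inputs), function(i) {
    if (isTiff[i]) {
      img <- readChannelImageTIFF(inputs[i], pixelSize = pixelSize)
      if (any(grepl("^ch[0-9]+$", channelNames(img))) && is.null(channelMap))
        stop("config error: TIFF input without channel names needs a channelMap")
      extractPointPattern(img, channelMap = channelMap, mode = mode)
    } else {
      p <- readPatternCSV(inputs[i], domain = dom)
      if (is.null(domain(p))) domain(p) <- computeLnBoundary(p)
      p
    }
  })
  ids <- sub("\\.[^.]+$", "", basename(inputs))
  if (length(patterns) == 1L) {
    warning("single sample: per-sample statistics only, no paired test")
    p <- patterns[[1L]]
    mi <- perPointMingling(p, k = config@kNeighbors)
    down <- downsamplePattern(p, config@downsampleFactor)
    vor <- mergeSameColorClusters(buildVoronoi(down, boundary = domain(p),
                                               computeTiles = FALSE))
    tab <- data.frame(sample_id = ids, mi_observed = meanMI(mi),
                      cells_per_cluster_observed = cellsPerCluster(vor))
    utils::write.csv(tab, file.path(outdir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(list(n_samples = 1L, verdict = NA,
                              mi_observed = meanMI(mi),
                              cells_per_cluster_observed = cellsPerCluster(vor)),
                         file.path(outdir, "report.json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(list(mi = mi, voronoi = vor)))
  }
  report <- analyzeCohort(patterns, config = config, statistics = statistics,
                          fastNull = fastNull, sampleIds = ids)
  writeReport(report, file.path(outdir, "report.csv"),
              file.path(outdir, "report.json"), config = config)
  invisible(report)
}
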