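#' Threshold an intensity channel into a binary mask
#'
#' Default is Otsu's method (deterministic, parameter-free); a manual
#' threshold can be supplied instead. Pixels strictly above the threshold
#' are positive. The threshold actually used is recorded in the mask for
#' provenance.
#'
#' @param channel numeric intensity matrix (or a [ChannelImage-class]
#'   together with `channelName`).
#' @param method `"otsu"` or `"manual"`.
#' @param manualValue threshold intensity, required iff `method = "manual"`.
#' @param pixelSize micrometres per pixel recorded in the mask (taken from
#'   the image when a [ChannelImage-class] is given).
#' @param channelName channel to threshold when `channel` is a
#'   [ChannelImage-class].
#' @return A [BinaryMask-class].
#' @examples
#' m <- matrix(0, 10, 10); m[3:7, 3:7] <- 100
#' sum(maskPixels(thresholdChannel(m, "manual", manualValue = 50)))  # 25
#' @export
thresholdChannel <- function(channel, method = c("otsu", "manual"),
                             manualValue = NULL, pixelSize = 1,
                             channelName = NULL) {
  method <- match.arg(method)
  if (is(channel, "ChannelImage")) {
    if (is.null(channelName)) stop("config error: channelName required for a ChannelImage")
    pixelSize <- channel@pixelSize
    channel <- getChannel(channel, channelName)
  }
  if (!is.matrix(channel) || length(channel) == 0L)
    stop("channel must be a non-empty matrix")
  if (method == "manual") {
    if (is.null(manualValue)) stop("config error: manualValue required for manual thresholding")
    thr <- as.numeric(manualValue)
  } else {
    rng <- range(channel)
    if (diff(rng) == 0)
      stop("degenerate threshold: channel has constant intensity")
    # EBImage's Otsu works on [0, 1]; rescale, threshold, map back
    scaled <- (channel - rng[1L]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
    thr <- rng[1L] + thr01 * diff(rng)
  }
  new("BinaryMask", pixels = channel > thr, pixelSize = pixelSize,
      threshold = thr, method = method)
}

#' @rdname accessors
#' @export
setMethod("maskPixels", "BinaryMask", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSize", "BinaryMask", function(x) x@pixelSize)

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %d positive (%.2f%%), threshold %.4g (%s)\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
              100 * mean(object@pixels), object@threshold,
              if (nzchar(object@method)) object@method else "none"))
})

#' Convert a multichannel image into a marked point pattern
#'
#' The imaging front-end of the clonality analysis. Each channel is
#' thresholded (Otsu by default) inside the optional LN mask. In `"pixel"`
#' mode every positive pixel becomes one point at its pixel centre - the
#' regime used for whole-LN analyses, where patterns reach hundreds of
#' thousands of points. In `"centroid"` mode each connected component of a
#' channel mask becomes a single point at its centroid, for cell-level data.
#' Pixels positive in more than one channel are resolved by
#' `multiPositive`: `"argmax"` keeps the channel with the highest intensity
#' (color reporters are nominally mutually exclusive, so ties are treated
#' as bleed-through), `"exclude"` drops the pixel.
#'
#' @param image a [ChannelImage-class].
#' @param channelMap optional named character vector renaming channels to
#'   color marks, e.g. `c(ch1 = "nGFP", ...)`; default uses channel names
#'   as marks.
#' @param lnMask optional [BinaryMask-class] restricting analysis to the
#'   tissue; must match the image shape.
#' @param mode `"pixel"` or `"centroid"`.
#' @param multiPositive `"argmax"` or `"exclude"`.
#' @param method,manualValue thresholding settings per
#'   [thresholdChannel()].
#' @param computeBoundary attach the convex hull of the points as the
#'   pattern's domain (requires >= 3 non-collinear points).
#' @return A [MarkedPointPattern-class] with coordinates in micrometres.
#' @export
extractPointPattern <- function(image, channelMap = NULL, lnMask = NULL,
                                mode = c("pixel", "centroid"),
                                multiPositive = c("argmax", "exclude"),
                                method = c("otsu", "manual"),
                                manualValue = NULL,
                                computeBoundary = TRUE) {
  stopifnot(is(image, "ChannelImage"))
  mode <- match.arg(mode)
  multiPositive <- match.arg(multiPositive)
  method <- match.arg(method)
  chans <- image@channels
  if (is.null(channelMap)) {
    channelMap <- stats::setNames(chans, chans)
  } else if (!all(chans %in% names(channelMap))) {
    stop("config error: channelMap is missing channel(s): ",
         paste(setdiff(chans, names(channelMap)), collapse = ", "))
  }
  d <- dim(image@data)
  if (!is.null(lnMask)) {
    if (!identical(dim(maskPixels(lnMask)), d[1:2]))
      stop("lnMask shape does not match the image")
    keepPx <- maskPixels(lnMask)
  } else {
    keepPx <- matrix(TRUE, d[1L], d[2L])
  }
  nch <- length(chans)
  pos <- vector("list", nch)
  npos <- matrix(0L, d[1L], d[2L])
  for (ch in seq_len(nch)) {
    msk <- thresholdChannel(image@data[, , ch], method = method,
                            manualValue = manualValue,
                            pixelSize = image@pixelSize)
    pos[[ch]] <- maskPixels(msk) & keepPx
    npos <- npos + pos[[ch]]
  }
  multi <- which(npos > 1L)
  if (length(multi)) {
    if (multiPositive == "exclude") {
      for (ch in seq_len(nch)) pos[[ch]][multi] <- FALSE
    } else {
      ints <- vapply(seq_len(nch),
                     function(ch) image@data[, , ch][multi], numeric(length(multi)))
      ints <- matrix(ints, ncol = nch)
      wasPos <- matrix(vapply(seq_len(nch), function(ch) pos[[ch]][multi],
                              logical(length(multi))), ncol = nch)
      ints[!wasPos] <- -Inf
      winner <- max.col(ints, ties.method = "first")
      for (ch in seq_len(nch)) pos[[ch]][multi] <- winner == ch
    }
  }
  ptsList <- vector("list", nch)
  for (ch in seq_len(nch)) {
    m <- pos[[ch]]
    if (!any(m)) { ptsList[[ch]] <- matrix(numeric(0), ncol = 2L); next }
    if (mode == "pixel") {
      idx <- which(m, arr.ind = TRUE)           # row, col (1-based)
      ptsList[[ch]] <- cbind(idx[, 2L] - 0.5, idx[, 1L] - 0.5)
    } else {
      lab <- EBImage::bwlabel(m)
      idx <- which(m, arr.ind = TRUE)
      ids <- lab[idx]
      cx <- tapply(idx[, 2L] - 0.5, ids, mean)
      cy <- tapply(idx[, 1L] - 0.5, ids, mean)
      ptsList[[ch]] <- cbind(as.numeric(cx), as.numeric(cy))
    }
  }
  counts <- vapply(ptsList, nrow, integer(1))
  if (sum(counts) == 0L) stop("empty pattern: no positive pixels in any channel")
  xy <- do.call(rbind, ptsList)
  xy <- cbind(image@origin[1L] + xy[, 1L] * image@pixelSize,
              image@origin[2L] + xy[, 2L] * image@pixelSize)
  mk <- rep(unname(channelMap[chans]), times = counts)
  pat <- markedPointPattern(xy, mk, domain = NULL,
                            colorLevels = unique(unname(channelMap[chans])))
  if (computeBoundary && nPoints(pat) >= 3L) {
    bnd <- tryCatch(computeLnBoundary(pat), error = function(e) NULL)
    if (!is.null(bnd)) domain(pat) <- bnd
  }
  pat
}

#' Convex-hull boundary of a point pattern
#'
#' The LN boundary is determined programmatically as the convex hull of all
#' points, regardless of color (the overlay of all reporters).
#'
#' @param pattern a [MarkedPointPattern-class] with at least 3 non-collinear
#'   points.
#' @return A [DomainPolygon-class]; every point of the pattern lies inside
#'   or on it.
#' @export
computeLnBoundary <- function(pattern) {
  stopifnot(is(pattern, "MarkedPointPattern"))
  xy <- coords(pattern)
  if (nrow(xy) < 3L) stop("degenerate hull: need at least 3 points")
  h <- grDevices::chull(xy[, 1L], xy[, 2L])   # clockwise order
  if (length(h) < 3L) stop("degenerate hull: points are collinear")
  v <- xy[rev(h), , drop = FALSE]             # reverse -> counter-clockwise
  if (.polySignedArea(v) <= 0) stop("degenerate hull: points are collinear")
  domainPolygon(v)
}

#' Area fraction of a thresholded signal inside a tissue mask
#'
#' The proportion of LN area positive for a signal (e.g. tdTomato),
#' computed as |signal AND lnMask| / |lnMask| - the "Area Fraction" readout
#' on a thresholded, binarized channel.
#'
#' @param signalMask,lnMask [BinaryMask-class] objects of identical shape;
#'   `lnMask` must contain at least one positive pixel.
#' @return An [AreaFractionResult-class].
#' @examples
#' ln <- new("BinaryMask", pixels = matrix(TRUE, 10, 10), pixelSize = 1,
#'           threshold = NA_real_, method = "")
#' sig <- matrix(FALSE, 10, 10); sig[1:5, 1:5] <- TRUE
#' sig <- new("BinaryMask", pixels = sig, pixelSize = 1,
#'            threshold = NA_real_, method = "")
#' areaFraction(sig, ln)@fraction  # 0.25
#' @export
areaFraction <- function(signalMask, lnMask) {
  stopifnot(is(signalMask, "BinaryMask"), is(lnMask, "BinaryMask"))
  if (!identical(dim(maskPixels(signalMask)), dim(maskPixels(lnMask))))
    stop("masks must have the same shape")
  ln <- maskPixels(lnMask)
  if (!any(ln)) stop("invalid mask: LN mask is empty")
  lnA <- sum(ln)
  posA <- sum(maskPixels(signalMask) & ln)
  new("AreaFractionResult", lnAreaPx = as.integer(lnA),
      positiveAreaPx = as.integer(posA), fraction = posA / lnA)
}

setMethod("show", "AreaFractionResult", function(object) {
  cat(sprintf("AreaFractionResult: %d / %d px positive, fraction %.4f\n",
              object@positiveAreaPx, object@lnAreaPx, object@fraction))
})
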