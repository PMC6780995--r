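test_that("manual thresholding produces the exact step-image mask", {
  ch <- matrix(0, 20, 20); ch[6:10, 6:10] <- 100
  m <- thresholdChannel(ch, "manual", manualValue = 50)
  expect_equal(sum(maskPixels(m)), 25L)
  expect_equal(m@threshold, 50)
})

test_that("Otsu's threshold separates a bimodal intensity image", {
  set.seed(8)
  ch <- matrix(c(rnorm(5000, 20, 5), rnorm(5000, 200, 5)), 100, 100)
  m <- thresholdChannel(ch, "otsu")
  expect_gt(m@threshold, 20)
  expect_lt(m@threshold, 200)
  # mask recovers the bright population
  expect_equal(sum(maskPixels(m)), 5000L, tolerance = 0.01)
})

test_that("constant channels cannot be Otsu-thresholded", {
  expect_error(thresholdChannel(matrix(3, 5, 5), "otsu"),
               "degenerate threshold")
  expect_error(thresholdChannel(matrix(1, 5, 5), "manual"), "manualValue")
})

test_that("pixel mode yields one point per positive pixel, centroid one per blob", {
  # a 13-px disc (radius 2) in the cRFP channel
  d <- domainPolygon(cbind(c(0, 30, 30, 0), c(0, 0, 30, 30)))
  p <- markedPointPattern(cbind(15.5, 12.5), "cRFP", d,
                          colorLevels = c("nGFP", "cRFP"))
  img <- renderPatternToImage(p, pixelSize = 1, spotRadius = 2,
                              backgroundNoiseSd = 0)
  px <- extractPointPattern(img, mode = "pixel", method = "manual",
                            manualValue = 0.5, computeBoundary = FALSE)
  expect_equal(nPoints(px), 13L)
  expect_true(all(marks(px) == "cRFP"))

  ce <- extractPointPattern(img, mode = "centroid", method = "manual",
                            manualValue = 0.5, computeBoundary = FALSE)
  expect_equal(nPoints(ce), 1L)
  expect_lt(max(abs(coords(ce) - c(15.5, 12.5))), 0.5 + 1e-9)
})

test_that("multi-positive pixels follow the argmax / exclude policy", {
  img <- new("ChannelImage",
             data = array(0, dim = c(5, 5, 2)),
             channels = c("cRFP", "cYFP"), pixelSize = 1, origin = c(0, 0))
  img@data[3, 3, 1] <- 80
  img@data[3, 3, 2] <- 120
  img@data[1, 1, 1] <- 90   # second cRFP-only pixel keeps Otsu happy
  am <- extractPointPattern(img, mode = "pixel", multiPositive = "argmax",
                            method = "manual", manualValue = 50,
                            computeBoundary = FALSE)
  expect_equal(as.character(marks(am)), c("cRFP", "cYFP"))
  ex <- extractPointPattern(img, mode = "pixel", multiPositive = "exclude",
                            method = "manual", manualValue = 50,
                            computeBoundary = FALSE)
  expect_equal(as.character(marks(ex)), "cRFP")  # contested pixel dropped
})

test_that("extraction respects the LN mask and missing channel maps error", {
  img <- new("ChannelImage", data = array(0, dim = c(4, 4, 1)),
             channels = "ch1", pixelSize = 1, origin = c(0, 0))
  img@data[, , 1] <- matrix(c(rep(100, 8), rep(0, 8)), 4, 4)
  ln <- new("BinaryMask", pixels = matrix(c(rep(TRUE, 4), rep(FALSE, 12)), 4, 4),
            pixelSize = 1, threshold = NA_real_, method = "")
  got <- extractPointPattern(img, channelMap = c(ch1 = "nGFP"), lnMask = ln,
                             mode = "pixel", method = "manual",
                             manualValue = 50, computeBoundary = FALSE)
  expect_equal(nPoints(got), 4L)
  expect_error(extractPointPattern(img, channelMap = c(wrong = "nGFP"),
                                   method = "manual", manualValue = 50),
               "config error")
  expect_error(extractPointPattern(img, channelMap = c(ch1 = "nGFP"),
                                   method = "manual", manualValue = 150),
               "empty pattern")
})

test_that("the noiseless render/extract round trip is exact for separated spots", {
  d <- domainPolygon(cbind(c(0, 200, 200, 0), c(0, 0, 120, 120)))
  # a grid of well-separated cells, mixed colors
  gx <- seq(15, 185, by = 22); gy <- seq(15, 105, by = 22)
  xy <- as.matrix(expand.grid(gx, gy))
  set.seed(3)
  mk <- sample(c("nGFP", "cRFP", "cYFP", "mCFP"), nrow(xy), replace = TRUE)
  p <- markedPointPattern(xy, mk, d)
  img <- renderPatternToImage(p, pixelSize = 1, spotRadius = 4,
                              backgroundNoiseSd = 0)
  got <- extractPointPattern(img, mode = "centroid", method = "manual",
                             manualValue = 0.5, computeBoundary = FALSE)
  expect_equal(nPoints(got), nPoints(p))
  expect_equal(as.integer(markCounts(got)), as.integer(markCounts(p)),
               ignore_attr = TRUE)
  # positions recovered within one pixel
  nn <- RANN::nn2(coords(got), coords(p), k = 1)
  expect_lt(max(nn$nn.dists), 1)
  matched <- marks(got)[nn$nn.idx[, 1]]
  expect_equal(as.character(matched), as.character(marks(p)))
})

test_that("the convex hull boundary contains all points and drops interior ones", {
  p <- markedPointPattern(rbind(c(0, 0), c(1, 0), c(0, 1), c(0.1, 0.1)),
                          c("A", "A", "B", "B"))
  h <- computeLnBoundary(p)
  expect_equal(nrow(vertices(h)), 3L)
  expect_equal(domainArea(h), 0.5)
  expect_true(all(insideDomain(h, coords(p))))

  expect_error(computeLnBoundary(markedPointPattern(cbind(c(0, 1), c(0, 1)),
                                                    c("A", "B"))),
               "degenerate hull")
  expect_error(computeLnBoundary(markedPointPattern(cbind(0:4, 0:4),
                                                    rep("A", 5))),
               "degenerate hull")
})

test_that("hulls of CSR points nearly fill the unit square and grow monotonically", {
  set.seed(44)
  p <- markedPointPattern(cbind(runif(1000), runif(1000)), rep("A", 1000))
  h <- computeLnBoundary(p)
  expect_lte(domainArea(h), 1)
  expect_gte(domainArea(h), 0.9)
  # adding a point never shrinks the hull
  for (i in 1:5) {
    q <- markedPointPattern(rbind(coords(p), cbind(runif(1), runif(1) + 0.5)),
                            rep("A", 1001))
    expect_gte(domainArea(computeLnBoundary(q)), domainArea(h) - 1e-12)
  }
})

test_that("area fraction is exact arithmetic on masks", {
  mk <- function(m) new("BinaryMask", pixels = m, pixelSize = 1,
                        threshold = NA_real_, method = "")
  ln <- mk(matrix(TRUE, 10, 10))
  sig <- matrix(FALSE, 10, 10); sig[1:5, 1:5] <- TRUE
  r <- areaFraction(mk(sig), ln)
  expect_equal(r@fraction, 0.25)
  expect_equal(r@lnAreaPx, 100L)

  expect_equal(areaFraction(mk(matrix(TRUE, 10, 10)), ln)@fraction, 1.0)
  expect_equal(areaFraction(mk(matrix(FALSE, 10, 10)), ln)@fraction, 0.0)

  # pixels outside the LN mask cannot change the fraction
  lnHalf <- matrix(FALSE, 10, 10); lnHalf[, 1:5] <- TRUE
  sig2 <- sig; sig2[, 6:10] <- TRUE
  expect_equal(areaFraction(mk(sig), mk(lnHalf))@fraction,
               areaFraction(mk(sig2), mk(lnHalf))@fraction)
  expect_error(areaFraction(mk(sig), mk(matrix(FALSE, 10, 10))),
               "invalid mask")
  expect_error(areaFraction(mk(sig), mk(matrix(TRUE, 3, 3))), "same shape")
})
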