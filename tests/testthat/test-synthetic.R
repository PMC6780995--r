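test_that("CSR simulation conserves per-color counts exactly and stays in-domain", {
  d <- unitSquareDomain()
  p <- simulateCSRPattern(d, c(A = 0, B = 0, C = 0, D = 1), seed = 1)
  expect_equal(nPoints(p), 1L)
  expect_equal(as.character(marks(p)), "D")
  expect_true(all(insideDomain(d, coords(p))))
  expect_equal(levels(marks(p)), c("A", "B", "C", "D"))

  ell <- testDomain()
  q <- simulateCSRPattern(ell, c(nGFP = 123, cRFP = 45, cYFP = 6, mCFP = 0),
                          seed = 9)
  expect_equal(as.integer(markCounts(q)), c(123L, 45L, 6L, 0L),
               ignore_attr = TRUE)
  expect_true(all(insideDomain(ell, coords(q))))
})

test_that("CSR simulation is reproducible under a fixed seed", {
  d <- unitSquareDomain()
  p1 <- simulateCSRPattern(d, c(A = 100, B = 100), seed = 42)
  p2 <- simulateCSRPattern(d, c(A = 100, B = 100), seed = 42)
  expect_identical(coords(p1), coords(p2))
  p3 <- simulateCSRPattern(d, c(A = 100, B = 100), seed = 43)
  expect_false(identical(coords(p1), coords(p3)))
})

test_that("CSR positions match uniform-distribution moments", {
  # mean of U(0,1) is 0.5 with sd (1/sqrt(12))/sqrt(n) for the sample mean
  d <- unitSquareDomain()
  p <- simulateCSRPattern(d, c(A = 10000), seed = 7)
  se <- (1 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(coords(p)[, 1]) - 0.5), 3 * se)
  expect_lt(abs(mean(coords(p)[, 2]) - 0.5), 3 * se)
})

test_that("CSR error cases are caught", {
  d <- unitSquareDomain()
  expect_error(simulateCSRPattern(d, c(A = 0, B = 0)), "empty pattern")
  expect_error(simulateCSRPattern("not a domain", c(A = 1)), "invalid domain")
  expect_error(simulateCSRPattern(d, c(A = -1, B = 2)), "non-negative")
})

test_that("clustered generator: no daughters means exactly the progenitors", {
  d <- testDomain()
  cfg <- clonalSimConfig(5, daughtersMean = 0, domain = d, seed = 3)
  p <- simulateClusteredPattern(cfg)
  expect_equal(nPoints(p), 5L)
  expect_true(all(insideDomain(d, coords(p))))
})

test_that("clustered generator reproduces the compound-process expectation", {
  # E[total] = n_progenitors * (1 + daughtersMean); check over replicates
  # against the Poisson-sum oracle: Var[total] = n * daughtersMean
  d <- testDomain()
  nRep <- 60
  totals <- vapply(seq_len(nRep), function(i) {
    nPoints(simulateClusteredPattern(
      clonalSimConfig(200, daughtersMean = 9, dispersionSigma = 10,
                      domain = d, seed = 500 + i)))
  }, numeric(1))
  expTotal <- 200 * (1 + 9)
  seTotal <- sqrt(200 * 9) / sqrt(nRep)
  expect_lt(abs(mean(totals) - expTotal), 4 * seTotal)
})

test_that("clustered generator draws parent colors from colorProbs", {
  d <- testDomain()
  cfg <- clonalSimConfig(4000, daughtersMean = 0, domain = d, seed = 11)
  p <- simulateClusteredPattern(cfg)
  fr <- as.numeric(markCounts(p)) / 4000
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(fr - 0.25) < 3.5 * se))
})

test_that("all clustered points stay inside the domain (resampled, not clipped)", {
  d <- makeEllipticalDomain(100, 60, 32)
  cfg <- clonalSimConfig(100, daughtersMean = 5, dispersionSigma = 40,
                         domain = d, seed = 21)
  p <- simulateClusteredPattern(cfg)
  expect_true(all(insideDomain(d, coords(p))))
  # counts preserved despite heavy resampling pressure
  expect_gte(nPoints(p), 100L)
})

test_that("invalid clustered configs are rejected", {
  d <- unitSquareDomain()
  expect_error(clonalSimConfig(3, colorProbs = c(A = 0.6, B = 0.6),
                               domain = d), "sum to 1")
  expect_error(clonalSimConfig(0, domain = d), "at least one progenitor")
  expect_error(simulateClusteredPattern("nope"), "config error")
})

test_that("degenerate alternative matches CSR on the mingling index", {
  # daughtersMean = 0 must be distributionally CSR: replicate mean MIs of
  # the two generators agree within 2 SE
  d <- testDomain()
  nRep <- 200
  miC <- miR <- numeric(nRep)
  for (i in seq_len(nRep)) {
    pc <- simulateClusteredPattern(clonalSimConfig(120, daughtersMean = 0,
                                                   domain = d, seed = 3000 + i))
    pr <- simulateCSRPattern(d, c(nGFP = 30, cRFP = 30, cYFP = 30, mCFP = 30),
                             seed = 7000 + i)
    miC[i] <- meanMI(perPointMingling(pc, 4))
    miR[i] <- meanMI(perPointMingling(pr, 4))
  }
  se <- sqrt(var(miC) / nRep + var(miR) / nRep)
  expect_lt(abs(mean(miC) - mean(miR)), 2 * se)
})

test_that("mean MI decreases as clones become more compact", {
  d <- testDomain()
  sigmas <- c(50, 20, 5)
  nRep <- 25
  means <- vapply(seq_along(sigmas), function(s) {
    mean(vapply(seq_len(nRep), function(i) {
      p <- simulateClusteredPattern(clonalSimConfig(
        100, daughtersMean = 9, dispersionSigma = sigmas[s],
        domain = d, seed = 100 * s + i))
      meanMI(perPointMingling(p, 4))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))  # sigma 50 -> 20 -> 5 shrinks mixing
})

test_that("rendering is deterministic and draws one disc per isolated point", {
  d <- unitSquareDomain()
  p <- markedPointPattern(cbind(0.5, 0.5), "cRFP", d, colorLevels = c("cRFP", "cYFP"))
  img <- renderPatternToImage(p, pixelSize = 0.05, spotRadius = 3,
                              backgroundNoiseSd = 0)
  ch <- getChannel(img, "cRFP")
  expect_true(any(ch > 0))
  expect_equal(sum(getChannel(img, "cYFP")), 0)
  # a single filled disc is one connected component
  expect_equal(max(EBImage::bwlabel(ch > 0)), 1)

  i1 <- renderPatternToImage(p, 0.05, 3, backgroundNoiseSd = 0.1, seed = 5)
  i2 <- renderPatternToImage(p, 0.05, 3, backgroundNoiseSd = 0.1, seed = 5)
  expect_identical(i1@data, i2@data)
})

test_that("rendering an empty pattern warns and returns a noise-only image", {
  d <- unitSquareDomain()
  p <- markedPointPattern(matrix(numeric(0), ncol = 2), character(0),
                          domain = d, colorLevels = c("A", "B"))
  expect_warning(img <- renderPatternToImage(p, 0.1, 2, backgroundNoiseSd = 0.01,
                                             seed = 1), "empty pattern")
  expect_equal(channelNames(img), c("A", "B"))
})
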