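test_that("downsampling keeps every color at the stated rounding rule", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(cRFP = 4000, cYFP = 2000, nGFP = 1000,
                               mCFP = 1000), seed = 2)
  ds <- downsamplePattern(p, 1000, seed = 3)
  expect_equal(as.integer(markCounts(ds)), c(4L, 2L, 1L, 1L),
               ignore_attr = TRUE)

  # round half away from zero: 1500/1000 -> 2
  q <- simulateCSRPattern(d, c(A = 1500), seed = 4)
  expect_equal(nPoints(downsamplePattern(q, 1000, seed = 5)), 2L)

  # a represented color is never dropped
  r <- simulateCSRPattern(d, c(A = 5000, B = 3), seed = 6)
  expect_equal(as.integer(markCounts(downsamplePattern(r, 1000, seed = 7))),
               c(5L, 1L), ignore_attr = TRUE)
})

test_that("downsampling with factor 1 is the identity and factor < 1 errors", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(A = 50, B = 20), seed = 8)
  expect_identical(coords(downsamplePattern(p, 1)), coords(p))
  expect_error(downsamplePattern(p, 0.5), "invalid parameter")
})

test_that("corner-square tessellation matches closed-form bisector geometry", {
  sq <- unitSquareDomain()
  p <- markedPointPattern(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                          c("A", "A", "B", "B"), sq)
  tess <- buildVoronoi(p, sq)
  expect_equal(nTiles(tess), 4L)
  expect_equal(tileAreas(tess), rep(0.25, 4))
  # edge-sharing neighbours only; diagonals meet at the centre vertex
  a <- adjacencyEdges(tess)
  expect_equal(nrow(a), 4L)
  expect_false(any(apply(a, 1, function(e) setequal(e, c(1, 3)))))
  expect_false(any(apply(a, 1, function(e) setequal(e, c(2, 4)))))

  res <- mergeSameColorClusters(tess)
  expect_equal(nTiles(res), 4L)
  expect_equal(nClusters(res), 2L)
  expect_equal(cellsPerCluster(res), 2.0)
})

test_that("two points split the domain along the perpendicular bisector", {
  sq <- unitSquareDomain()
  p <- markedPointPattern(cbind(c(0.25, 0.75), c(0.5, 0.5)), c("A", "B"), sq)
  tess <- buildVoronoi(p, sq)
  expect_equal(tileAreas(tess), c(0.5, 0.5))
  expect_equal(sum(tileAreas(tess)), domainArea(sq))
})

test_that("tiles partition the domain for CSR patterns", {
  d <- testDomain()
  for (n in c(25, 400)) {
    p <- simulateCSRPattern(d, c(A = n, B = n), seed = n)
    tess <- buildVoronoi(p)
    expect_lt(abs(sum(tileAreas(tess)) - domainArea(d)) / domainArea(d), 1e-6)
  }
})

test_that("duplicate points merge with a warning; conflicting colors error", {
  sq <- unitSquareDomain()
  xy <- rbind(c(0.2, 0.2), c(0.2, 0.2), c(0.8, 0.8))
  expect_warning(tess <- buildVoronoi(
    markedPointPattern(xy, c("A", "A", "B"), sq), sq), "duplicate")
  expect_equal(nTiles(tess), 2L)
  expect_error(suppressWarnings(buildVoronoi(
    markedPointPattern(xy, c("A", "B", "B"), sq), sq)), "duplicate conflict")
  expect_error(buildVoronoi(
    markedPointPattern(cbind(0.5, 0.5), "A", sq), sq), "degenerate")
})

test_that("monochrome and all-distinct colorings hit the merging extremes", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(A = 40), seed = 12)
  res <- mergeSameColorClusters(buildVoronoi(p))
  expect_equal(nClusters(res), 1L)            # convex-domain Voronoi adjacency is connected
  expect_equal(cellsPerCluster(res), 40)

  q <- simulateCSRPattern(d, c(A = 1, B = 1, C = 1, D = 1), seed = 13)
  res4 <- mergeSameColorClusters(buildVoronoi(q))
  expect_equal(nClusters(res4), 4L)
  expect_equal(cellsPerCluster(res4), 1.0)
})

test_that("cluster areas partition each color's tile area", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(A = 60, B = 60), seed = 14)
  tess <- buildVoronoi(p)
  res <- mergeSameColorClusters(tess)
  areas <- tileAreas(tess)
  mk <- marks(tess)
  for (lv in levels(mk)) {
    colorTiles <- which(mk == lv)
    clusterIds <- unique(res@membership[colorTiles])
    inClusters <- sum(areas[res@membership %in% clusterIds])
    expect_equal(inClusters, sum(areas[colorTiles]), tolerance = 1e-9)
  }
  expect_equal(sum(clusterSizes(res)), nTiles(res))
})

test_that("adjacency-only and full tessellation give the same statistic", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(A = 80, B = 40, C = 40), seed = 15)
  full <- mergeSameColorClusters(buildVoronoi(p, computeTiles = TRUE))
  fast <- mergeSameColorClusters(buildVoronoi(p, computeTiles = FALSE))
  expect_equal(cellsPerCluster(full), cellsPerCluster(fast))
  expect_equal(full@membership, fast@membership)
})

test_that("cluster merging agrees with the bisector-interval oracle", {
  d <- makeEllipticalDomain(10, 7, 24)
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    p <- simulateCSRPattern(d, c(A = n %/% 2 + 1, B = n - n %/% 2 - 1 + 1))
    tess <- buildVoronoi(p, computeTiles = FALSE)
    oracleEdges <- bisectorAdjacencyOracle(coords(p), vertices(d))
    # same adjacency set
    gotE <- adjacencyEdges(tess)
    expect_equal(gotE[order(gotE[, 1], gotE[, 2]), , drop = FALSE],
                 oracleEdges[order(oracleEdges[, 1], oracleEdges[, 2]), ,
                             drop = FALSE],
                 ignore_attr = TRUE)
    # same same-color components
    mk <- as.integer(marks(p))
    sameColor <- oracleEdges[mk[oracleEdges[, 1]] == mk[oracleEdges[, 2]], ,
                             drop = FALSE]
    oracleMemb <- unionFindComponents(nPoints(p), sameColor)
    got <- mergeSameColorClusters(tess)
    expect_equal(max(oracleMemb), nClusters(got))
    # identical partitions up to label permutation
    expect_equal(length(unique(paste(oracleMemb, got@membership))),
                 nClusters(got))
  }
})
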