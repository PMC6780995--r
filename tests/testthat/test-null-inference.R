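test_that("randomization preserves per-color counts and the boundary", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(nGFP = 37, cRFP = 12, cYFP = 5, mCFP = 1),
                          seed = 1)
  nul <- randomizePattern(p, seed = 2)
  expect_equal(markCounts(nul), markCounts(p))
  expect_true(all(insideDomain(d, coords(nul))))
  expect_false(identical(coords(nul), coords(p)))
  n2 <- randomizePattern(p, seed = 3)
  expect_false(identical(coords(nul), coords(n2)))
  expect_identical(coords(randomizePattern(p, seed = 2)), coords(nul))

  noDom <- markedPointPattern(coords(p), marks(p))
  expect_error(randomizePattern(noDom), "no boundary")
})

test_that("the mark-permutation null keeps positions and matches its expectation", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(A = 120, B = 60, C = 20), seed = 71)
  perm <- randomizePattern(p, seed = 72, method = "permute")
  expect_identical(coords(perm), coords(p))
  expect_equal(markCounts(perm), markCounts(p))
  expect_false(identical(marks(perm), marks(p)))
  # permutation-null MI concentrates on 1 - sum n_c(n_c-1)/(n(n-1))
  ens <- nullMinglingEnsemble(p, analysisConfig(nNullIterationsMi = 50,
                                                seed = 73),
                              method = "permute")
  counts <- c(120, 60, 20); n <- 200
  expected <- 1 - sum(counts * (counts - 1)) / (n * (n - 1))
  se <- sd(nullValues(ens)) / sqrt(50)
  expect_lt(abs(nullSummary(ens) - expected), 4 * se)
})

test_that("monochrome patterns have MI 0 under any randomization", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(A = 60), seed = 4)
  ens <- nullMinglingEnsemble(p, analysisConfig(seed = 5))
  expect_equal(nullValues(ens), rep(0, 10))
  expect_equal(nullSummary(ens), 0)
})

test_that("null ensembles are reproducible and summarize by the mean", {
  d <- testDomain()
  p <- simulateCSRPattern(d, c(A = 200, B = 200), seed = 6)
  e1 <- nullMinglingEnsemble(p, analysisConfig(seed = 7))
  e2 <- nullMinglingEnsemble(p, analysisConfig(seed = 7))
  expect_identical(nullValues(e1), nullValues(e2))
  expect_equal(nullSummary(e1), mean(nullValues(e1)))
  expect_equal(length(nullValues(e1)), 10L)
})

test_that("Voronoi null ensemble hits its degenerate limits", {
  d <- testDomain()
  one <- simulateCSRPattern(d, c(A = 1, B = 1, C = 1, D = 1), seed = 8)
  cfg <- analysisConfig(downsampleFactor = 1, seed = 9)
  ens <- nullVoronoiEnsemble(one, cfg)
  expect_equal(nullValues(ens), rep(1.0, 10))     # no same-color pairs possible

  mono <- simulateCSRPattern(d, c(A = 25), seed = 10)
  ensM <- nullVoronoiEnsemble(mono, cfg)
  expect_equal(nullValues(ensM), rep(25, 10))     # monochrome merges to one cluster
})

test_that("exact and direct Voronoi null draws have the same distribution", {
  # uniform subsampling of uniform points is uniform: the full-size re-draw
  # + downsample path and the direct draw at downsampled counts must give
  # statistically indistinguishable cells-per-cluster
  d <- testDomain()
  p <- simulateCSRPattern(d, c(A = 30000, B = 30000, C = 30000, D = 30000),
                          seed = 11)
  cfg <- function(s) analysisConfig(nNullIterationsVoronoi = 60, seed = s)
  ve <- nullValues(nullVoronoiEnsemble(p, cfg(12), exact = TRUE))
  vf <- nullValues(nullVoronoiEnsemble(p, cfg(13), exact = FALSE))
  se <- sqrt(var(ve) / 60 + var(vf) / 60)
  expect_lt(abs(mean(ve) - mean(vf)), 3 * se)
})

test_that("the paired test matches its closed form and reports direction", {
  obs <- c(0.60, 0.62, 0.58, 0.61)
  nul <- c(0.75, 0.74, 0.76, 0.73)
  cmp <- pairedObservedVsNull(obs, nul)
  dd <- obs - nul
  tExp <- mean(dd) / (sd(dd) / sqrt(4))
  pExp <- 2 * pt(-abs(tExp), df = 3)
  expect_equal(cmp@tStatistic, tExp)
  expect_equal(cmp@pValue, pExp)
  expect_equal(cmp@direction, "observed_lower")

  rev <- pairedObservedVsNull(nul, obs)
  expect_equal(rev@direction, "observed_higher")
  expect_equal(rev@pValue, cmp@pValue)
})

test_that("degenerate paired inputs are rejected", {
  expect_error(pairedObservedVsNull(c(1, 2, 3), c(1, 2, 3)), "degenerate test")
  expect_error(pairedObservedVsNull(c(1, 2, 3), c(2, 3, 4)), "degenerate test")
  expect_error(pairedObservedVsNull(c(1, 2), c(1, 2, 3)), "input error")
  expect_error(pairedObservedVsNull(1, 2), "input error")
})

test_that("clusteringReport combines both statistics into a verdict", {
  miObs <- c(0.60, 0.62, 0.58, 0.61, 0.59)
  miNul <- c(0.75, 0.74, 0.76, 0.73, 0.75)
  voObs <- c(3.2, 2.9, 3.5, 3.1, 3.0)
  voNul <- c(2.1, 2.2, 2.0, 2.15, 2.1)
  rep1 <- clusteringReport(paste0("LN", 1:5), miObs, miNul, voObs, voNul)
  expect_s4_class(rep1, "ClonalityReport")
  expect_equal(rep1@verdict, "clustered")
  expect_equal(nrow(rep1@table), 5L)
  expect_named(rep1@table, c("sample_id", "mi_observed", "mi_null",
                             "cells_per_cluster_observed",
                             "cells_per_cluster_null"))

  # discordant directions cannot be called clustered
  rep2 <- clusteringReport(paste0("LN", 1:5), miNul, miObs, voObs, voNul)
  expect_equal(rep2@verdict, "not clustered")
  expect_error(clusteringReport("LN1", 0.5, 0.7, 2, 2.2), "input error")
})
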