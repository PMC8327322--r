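test_that("bin-count heuristic is round-half-up n^(2/5) floored at 2", {
  expect_equal(chooseBinCount(32), 4L)    # 32^(2/5) = 4 exactly
  expect_equal(chooseBinCount(243), 9L)   # 243^(2/5) = 9 exactly
  expect_equal(chooseBinCount(100), 6L)   # 100^0.4 = 6.3096
  expect_equal(chooseBinCount(0), 2L)
  expect_equal(chooseBinCount(1), 2L)
})

test_that("positions are assigned to equal-length bins", {
  expect_equal(binPositions(c(1, 25, 26, 100), 100, 4), c(2L, 1L, 0L, 1L))
  expect_equal(binPositions(integer(0), 100, 4), integer(4))
  set.seed(5)
  for (i in 1:5) {
    pos <- sample.int(777, 60, TRUE)
    k <- sample(2:9, 1)
    expect_equal(sum(binPositions(pos, 777, k)), 60L)
  }
  expect_error(binPositions(c(1, 101), 100, 4), "1, L")
})

test_that("coverage adjustment divides by mean bin coverage", {
  expect_equal(adjustBinCounts(c(4, 2), rep(1, 100), 100), c(4, 2))
  expect_equal(adjustBinCounts(c(4, 2), rep(0.5, 100), 100), c(8, 4))
  # piecewise coverage against brute-force per-bin means
  cov <- c(rep(0.8, 50), rep(0.4, 50))
  got <- adjustBinCounts(c(3, 6, 9, 12), cov, 100)
  idx <- pmin(4, ceiling(seq_len(100) * 4 / 100))
  want <- c(3, 6, 9, 12) /
    sapply(1:4, function(j) mean(cov[idx == j]))
  expect_equal(got, want)
})

test_that("BIN-test recovers the hand-computed chi-squared table", {
  bt <- binTest(twoBlockDataset())
  expect_equal(bt$k, 4L)                     # 40^(2/5) rounds to 4
  expect_equal(bt$statistic, 40)             # eight cells of (5)^2/5
  expect_equal(bt$df, 3L)
  expect_equal(bt$p.value, pchisq(40, 3, lower.tail = FALSE))
  expect_lt(abs(bt$p.value - 1.1e-8), 2e-9)
})

test_that("identical positional distributions give statistic 0, p 1", {
  ds <- makeDataset(c(10L, 35L, 60L, 85L), c(10L, 35L, 60L, 85L),
                    caseCounts = 5L, ctrlCounts = 5L)
  bt <- binTest(ds)
  expect_equal(bt$statistic, 0)
  expect_equal(bt$p.value, 1)
})

test_that("bins with zero combined counts are dropped with df reduction", {
  # bins: case (10, 0, 10, 0), control (10, 0, 0, 10) -> bin 2 empty
  ds <- makeDataset(c(10L, 60L), c(10L, 90L), caseCounts = 10L,
                    ctrlCounts = 10L)
  bt <- binTest(ds)
  expect_equal(bt$k, 4L)
  expect_equal(bt$kRetained, 3L)
  expect_equal(bt$df, 2L)
})

test_that("degenerate tables return p 1 with a warning", {
  ds <- makeDataset(10L, 12L, caseCounts = 3L, ctrlCounts = 3L)
  expect_warning(bt <- binTest(ds), "degenerate")
  expect_equal(bt$p.value, 1)
  expect_equal(bt$df, 0L)
  expect_true(bt$degenerate)
})

test_that("the statistic is invariant to mirroring the protein", {
  ds <- makeDataset(c(7L, 33L, 41L, 88L), c(15L, 52L, 60L, 95L),
                    caseCounts = c(4L, 6L, 2L, 8L),
                    ctrlCounts = c(5L, 5L, 5L, 5L))
  mirrored <- makeDataset(101L - c(7L, 33L, 41L, 88L),
                          101L - c(15L, 52L, 60L, 95L),
                          caseCounts = c(4L, 6L, 2L, 8L),
                          ctrlCounts = c(5L, 5L, 5L, 5L))
  expect_equal(binTest(ds)$statistic, binTest(mirrored)$statistic)
})

test_that("coverage-adjusted counts feed the statistic directly", {
  ds <- twoBlockDataset()
  # uniform coverage leaves the test unchanged
  dsU <- makeDataset(c(10L, 40L), c(60L, 90L), caseCounts = 10L,
                     ctrlCounts = 10L,
                     coverageCase = rep(1, 100),
                     coverageControl = rep(1, 100))
  expect_equal(binTest(dsU, useCoverage = TRUE)$statistic,
               binTest(ds)$statistic)
  # halving control coverage doubles control counts in the table
  dsH <- makeDataset(c(10L, 40L), c(60L, 90L), caseCounts = 10L,
                     ctrlCounts = 10L,
                     coverageControl = rep(0.5, 100))
  tab <- binTable(dsH, useCoverage = TRUE)
  expect_equal(tab@countsControl, c(0, 0, 20, 20))
  expect_true(tab@adjusted)
})

test_that("null-simulation BIN-test p-values are approximately uniform", {
  sc <- SimulationScenario("null")
  p <- vapply(1:400, function(i) {
    suppressWarnings(
      binTest(simulateGene(sc, seed = 5000 + i)@dataset))$p.value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
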