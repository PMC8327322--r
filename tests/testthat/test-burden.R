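test_that("one-sided burden p matches the hypergeometric tail", {
  ds <- makeDataset(1:5, integer(0), nCase = 10L, nCtrl = 10L)
  # P(all 5 carriers fall in the 10 cases) = C(10,5)/C(20,5)
  expect_equal(burdenTest(ds)$p.value, 252 / 15504, tolerance = 1e-12)
})

test_that("no case carriers gives p 1 (enrichment direction only)", {
  ds <- makeDataset(integer(0), c(5L, 9L), nCase = 50L, nCtrl = 50L)
  expect_equal(burdenTest(ds)$p.value, 1)
})

test_that("burden p agrees with Fisher's exact test on random tables", {
  set.seed(21)
  for (i in 1:20) {
    nCase <- sample(20:200, 1)
    nCtrl <- sample(20:200, 1)
    a <- sample(0:10, 1)
    cc <- sample(0:10, 1)
    v <- rbind(if (a > 0) makeVariants(seq_len(a), "case"),
               if (cc > 0) makeVariants(seq_len(cc), "control"))
    if (is.null(v)) next
    ds <- GeneDataset("g", 300L, nCase, nCtrl, v)
    tab <- matrix(c(a, nCase - a, cc, nCtrl - cc), nrow = 2)
    expect_equal(burdenTest(ds)$p.value,
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("coverage adjustment rescales the effective cohort sizes", {
  full <- makeDataset(1:4, 5:6, nCase = 100L, nCtrl = 100L,
                      coverageCase = rep(1, 100),
                      coverageControl = rep(1, 100))
  expect_equal(burdenTest(full, useCoverage = TRUE)$p.value,
               burdenTest(full)$p.value)
  half <- makeDataset(1:4, 5:6, nCase = 100L, nCtrl = 100L,
                      coverageCase = rep(0.5, 100),
                      coverageControl = rep(0.5, 100))
  bt <- burdenTest(half, useCoverage = TRUE)
  expect_equal(bt$nCasesEffective, 50L)
  expect_equal(bt$nControlsEffective, 50L)
  # carriers exceeding the shrunken cohort is an error
  tiny <- makeDataset(1:40, 5:6, nCase = 41L, nCtrl = 100L,
                      coverageCase = rep(0.5, 100))
  expect_error(burdenTest(tiny, useCoverage = TRUE), "exceed")
})

test_that("Fisher's method matches its closed form and chi-squared tail", {
  expect_equal(fishersMethod(1, 1), 1)
  expect_equal(fishersMethod(0.05, 0.05), 0.01747866, tolerance = 1e-6)
  expect_equal(fishersMethod(0.5, 1), 0.8465736, tolerance = 1e-6)
  expect_error(fishersMethod(0, 0.5), "0, 1")
  expect_error(fishersMethod(0.5, 1.2), "0, 1")
  # closed form equals the chi-squared(4) survival function
  set.seed(8)
  p1 <- runif(1000, 1e-12, 1)
  p2 <- runif(1000, 1e-12, 1)
  X <- -2 * (log(p1) + log(p2))
  expect_equal(mapply(fishersMethod, p1, p2),
               pchisq(X, 4, lower.tail = FALSE), tolerance = 1e-12)
  # spot checks against numerical integration of the chi-squared(4)
  # density, an oracle independent of both closed forms
  for (i in 1:20) {
    Xi <- X[i]
    tail <- integrate(function(x) dchisq(x, 4), Xi, Inf,
                      rel.tol = 1e-12)$value
    expect_equal(fishersMethod(p1[i], p2[i]), tail, tolerance = 1e-9)
  }
})

test_that("combined p is monotone in each component", {
  grid <- c(0.001, 0.01, 0.1, 0.5, 1)
  for (p2 in grid) {
    out <- vapply(grid, fishersMethod, numeric(1), p2 = p2)
    expect_true(all(diff(out) >= 0))
  }
})

test_that("clusterBurden combines the component tests", {
  ds <- twoBlockDataset()
  res <- clusterBurden(ds)
  expect_s4_class(res, "TestResult")
  expect_equal(pCombined(res),
               fishersMethod(pBurden(res), pCluster(res)))
  expect_equal(res@statCluster, 40)
  expect_false(res@degenerate)
  df <- as.data.frame(res)
  expect_equal(df$p_combined, pCombined(res))
})

test_that("a degenerate BIN-test falls back to the burden p-value", {
  ds <- makeDataset(c(10L, 10L, 10L), 12L, nCase = 100L, nCtrl = 100L)
  res <- clusterBurden(ds)
  expect_true(res@degenerate)
  expect_equal(pCombined(res), pBurden(res))
  expect_equal(pCluster(res), 1)
})
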