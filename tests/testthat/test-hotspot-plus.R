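simWithScores <- function(seed, effect = 2, nFeatures = 6L) {
  sim <- simulateGene(SimulationScenario("single_cluster"), seed = seed)
  X <- generateSyntheticScores(sim, nFeatures = nFeatures,
                               informative = c("1" = effect),
                               seed = seed + 1)
  list(sim = sim, fr = assembleGamFrame(sim@dataset), X = X)
}

test_that("synthetic scores are deterministic and truth-aligned", {
  sim <- simulateGene(SimulationScenario("single_cluster"), seed = 23)
  X1 <- generateSyntheticScores(sim, nFeatures = 4,
                                informative = c("2" = 3), seed = 5)
  X2 <- generateSyntheticScores(sim, nFeatures = 4,
                                informative = c("2" = 3), seed = 5)
  expect_identical(X1, X2)
  expect_equal(ncol(X1), 4L)
  expect_equal(nrow(X1), sum(variantTable(sim@dataset)$carrier_count))
  tl <- attr(X1, "true_log_or")
  # the informative column tracks the truth, the others do not
  expect_gt(cor(X1[, 2], tl), 0.5)
  expect_lt(max(abs(cor(X1[, c(1, 3, 4)], tl))), 0.15)
})

test_that("zero effect sizes give truth-independent columns", {
  sim <- simulateGene(SimulationScenario("single_cluster"), seed = 29)
  X <- generateSyntheticScores(sim, nFeatures = 5, seed = 7)
  expect_lt(max(abs(cor(X, attr(X, "true_log_or")))), 0.15)
})

test_that("stage-1 Bonferroni threshold follows the candidate count", {
  s <- simWithScores(31)
  sel <- selectFeatures(s$fr, s$X, basisDim = 8L)
  expect_equal(sel$stage1_alpha, 0.05 / 6)
  expect_equal(signif(0.05 / 24, 1), 0.002)   # default candidate count
  expect_true(all(sel$final_features %in% sel$stage1_selected))
})

test_that("an informative feature is selected, noise is not", {
  for (s in c(41, 43, 47)) {
    sw <- simWithScores(s, effect = 2)
    sel <- selectFeatures(sw$fr, sw$X, basisDim = 8L)
    expect_equal(which.min(sel$stage1_pvalues), c(feature_01 = 1L))
    expect_true("feature_01" %in% sel$final_features)
  }
})

test_that("pure-noise candidate sets are (almost) never selected", {
  picks <- vapply(1:5, function(s) {
    sim <- simulateGene(SimulationScenario("single_cluster"),
                        seed = 300 + s)
    X <- generateSyntheticScores(sim, nFeatures = 8, seed = 400 + s)
    fr <- assembleGamFrame(sim@dataset)
    length(selectFeatures(fr, X, basisDim = 8L)$final_features)
  }, numeric(1))
  expect_gte(sum(picks == 0), 4)
})

test_that("hotspot+ with no features is exactly the hotspot model", {
  s <- simWithScores(53)
  m0 <- fitHotspot(s$fr)
  m1 <- fitHotspotPlus(s$fr, s$X, character(0))
  at <- seq(10L, 490L, by = 40L)
  expect_equal(predictPositionOR(m1, at)$log_or,
               predictPositionOR(m0, at)$log_or, tolerance = 1e-10)
})

test_that("feature terms stratify variants at the same position", {
  s <- simWithScores(59)
  m <- fitHotspotPlus(s$fr, s$X, "feature_01")
  two <- data.frame(position = c(137L, 137L),
                    feature_01 = c(-2, 2))
  pr <- predictVariantOR(m, two)
  expect_gt(abs(diff(pr$log_or)), 1e-6)
  # and a missing score falls back to the training mean
  one <- predictVariantOR(m, data.frame(position = 137L))
  atMean <- predictVariantOR(
    m, data.frame(position = 137L,
                  feature_01 = m@featureMeans[["feature_01"]]))
  expect_equal(one$log_or, atMean$log_or, tolerance = 1e-12)
})

test_that("selection p-values are invariant to affine feature rescaling", {
  s <- simWithScores(61, nFeatures = 3L)
  selA <- selectFeatures(s$fr, s$X, basisDim = 8L)
  X2 <- s$X
  X2[, 1] <- 100 * X2[, 1] - 7
  selB <- selectFeatures(s$fr, X2, basisDim = 8L)
  expect_equal(unname(selA$stage1_pvalues),
               unname(selB$stage1_pvalues), tolerance = 1e-8)
})

test_that("collinear features are refused by name", {
  s <- simWithScores(67, nFeatures = 3L)
  X <- s$X
  X[, 2] <- 2 * X[, 1]
  expect_error(fitHotspotPlus(s$fr, X,
                              c("feature_01", "feature_02")),
               "collinear")
})

test_that("a known feature effect is recovered within its uncertainty", {
  hits <- vapply(1:8, function(s) {
    rec <- makeRecoveryFrame(800 + s, gamma = 1)
    m <- fitHotspotPlus(rec$frame, rec$X, "feature_01")
    g <- coef(m@fit)["feature_01"]
    se <- sqrt(diag(vcov(m@fit))["feature_01"])
    abs(g - 1) < 2 * se
  }, logical(1))
  expect_gte(sum(hits), 7)
})

test_that("held-out AUC is at chance for noise and perfect for an
           oracle score", {
  sim <- simulateGene(SimulationScenario("null"), seed = 71)
  Xn <- generateSyntheticScores(sim, nFeatures = 1, seed = 72)
  fr <- assembleGamFrame(sim@dataset)
  chance <- crossfoldAUC(fr, Xn, "feature_01", useSmooth = FALSE,
                         seed = 73)
  expect_lt(abs(chance$mean_auc - 0.5), 0.12)
  # an oracle feature equal to the outcome ranks perfectly
  d <- fr@frame
  Xo <- matrix(d$is_case[d$carrier == 1], ncol = 1,
               dimnames = list(NULL, "feature_01"))
  suppressWarnings(
    perfect <- crossfoldAUC(fr, Xo, "feature_01", useSmooth = FALSE,
                            seed = 74))
  expect_equal(perfect$per_split_auc, rep(1, 10))
  expect_equal(perfect$n_splits, 10L)
})

test_that("positional and score information raise the AUC in order", {
  s <- simWithScores(79, effect = 2)
  plus <- crossfoldAUC(s$fr, s$X, "feature_01", seed = 80)
  spot <- crossfoldAUC(s$fr, seed = 80)
  noise <- crossfoldAUC(s$fr, s$X, "feature_02", useSmooth = FALSE,
                        seed = 80)
  expect_gte(plus$mean_auc, spot$mean_auc - 0.02)
  expect_gt(spot$mean_auc, noise$mean_auc)
})
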