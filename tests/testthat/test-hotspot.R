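test_that("the GAM frame does carrier and weight bookkeeping", {
  set.seed(14)
  ds <- makeDataset(sample(1:100, 12), sample(1:100, 18),
                    nCase = 100L, nCtrl = 1000L)
  fr <- assembleGamFrame(ds)
  d <- fr@frame
  expect_equal(nrow(d), 32L)          # 30 carriers + 2 aggregate rows
  agg <- d[d$carrier == 0, ]
  expect_equal(agg$weight[agg$is_case == 1], 100 - 12)
  expect_equal(agg$weight[agg$is_case == 0], 1000 - 18)
  expect_true(all(d$weight[d$carrier == 1] == 1))
  # total weight per cohort equals the cohort size at full coverage
  expect_equal(sum(d$weight[d$is_case == 1]), 100)
  expect_equal(sum(d$weight[d$is_case == 0]), 1000)
})

test_that("half coverage doubles every weight", {
  set.seed(15)
  ds1 <- makeDataset(sample(1:100, 12), sample(1:100, 18),
                     nCase = 100L, nCtrl = 1000L,
                     coverageCase = rep(1, 100),
                     coverageControl = rep(1, 100))
  ds2 <- ds1
  ds2@coverageCase <- rep(0.5, 100)
  ds2@coverageControl <- rep(0.5, 100)
  w1 <- assembleGamFrame(ds1)@frame$weight
  w2 <- assembleGamFrame(ds2)@frame$weight
  expect_equal(w2, 2 * w1)
})

test_that("too few carriers is refused unless forced", {
  ds <- makeDataset(1:5, 6:10)
  expect_error(assembleGamFrame(ds), "too few")
  expect_s4_class(assembleGamFrame(ds, force = TRUE), "GamFrame")
})

test_that("quasi-complete separation is an explicit error", {
  ds <- makeDataset(sample(1:100, 25), integer(0))
  fr <- assembleGamFrame(ds)
  expect_error(fitHotspot(fr), "separation")
})

test_that("an infinite penalty reduces to linear logistic regression", {
  sim <- simulateGene(SimulationScenario("single_cluster"), seed = 42)
  fr <- assembleGamFrame(sim@dataset)
  m <- fitHotspot(fr, sp = 1e10)
  d <- fr@frame
  g <- glm(is_case ~ carrier + carrier:position, family = binomial,
           weights = weight, data = d)
  pos <- c(25L, 137L, 300L, 480L)
  gamOR <- predictPositionOR(m, pos)$log_or
  glmOR <- unname(coef(g)["carrier"] + coef(g)["carrier:position"] * pos)
  expect_equal(gamOR, glmOR, tolerance = 1e-6)
})

test_that("an unpenalized fit on few distinct positions matches the
           dummy-encoded refit", {
  set.seed(10)
  posLevels <- c(50L, 150L, 250L, 350L, 450L)
  pos <- sample(posLevels, 200, replace = TRUE)
  eta <- c(`50` = 0, `150` = 1.5, `250` = 0.5, `350` = -0.5,
           `450` = 2)[as.character(pos)]
  isCase <- rbinom(200, 1, plogis(-1.5 + eta))
  v <- rbind(makeVariants(pos[isCase == 1], "case"),
             makeVariants(pos[isCase == 0], "control"))
  ds <- GeneDataset("toy", 500L, 1000L, 1000L, v)
  fr <- assembleGamFrame(ds)
  m <- fitHotspot(fr, basisDim = 5L, sp = 0)
  p <- predictPositionOR(m, posLevels)
  d <- fr@frame
  for (pp in posLevels)
    d[[paste0("P", pp)]] <- as.numeric(d$carrier == 1 & d$position == pp)
  suppressWarnings(
    g <- glm(is_case ~ P50 + P150 + P250 + P350 + P450,
             family = binomial, weights = weight, data = d))
  expect_equal(p$log_or,
               unname(coef(g)[paste0("P", posLevels)]),
               tolerance = 1e-6)
})

test_that("prediction reproduces the fitted linear predictor", {
  sim <- simulateGene(SimulationScenario("single_cluster"), seed = 19)
  fr <- assembleGamFrame(sim@dataset)
  m <- fitHotspot(fr)
  d <- fr@frame
  lp <- as.numeric(predict(m@fit, type = "link"))
  base <- lp[d$carrier == 0][1]
  carriers <- which(d$carrier == 1)
  pred <- predictPositionOR(m, d$position[carriers])
  expect_equal(pred$log_or, lp[carriers] - base, tolerance = 1e-10)
  # confidence bounds strictly bracket the estimate
  expect_true(all(pred$ci_low < pred$or & pred$or < pred$ci_high))
  expect_error(predictPositionOR(m, 501L), "1, L")
})

test_that("a zero-coefficient model predicts OR 1 everywhere", {
  sim <- simulateGene(SimulationScenario("null"), seed = 3)
  m <- fitHotspot(assembleGamFrame(sim@dataset))
  m@fit$coefficients[] <- 0
  p <- predictPositionOR(m, c(1L, 250L, 500L))
  expect_equal(p$or, rep(1, 3))
  expect_equal(p$log_or, rep(0, 3))
})

test_that("null data recover a flat smooth and a null carrier effect", {
  res <- vapply(1:30, function(s) {
    sim <- simulateGene(SimulationScenario("null"), seed = 6000 + s)
    m <- fitHotspot(assembleGamFrame(sim@dataset))
    b1 <- coef(m@fit)["carrier"]
    se <- sqrt(diag(vcov(m@fit))["carrier"])
    c(covered = unname(abs(b1) < 2 * se), edf = modelEDF(m))
  }, numeric(2))
  # the carrier effect is null and the typical smooth is (near-)linear;
  # REML occasionally spends a little extra edf on noise, so the tail is
  # assessed via the median
  expect_gte(mean(res["covered", ]), 0.85)
  expect_lt(median(res["edf", ]), 1.2)
})

test_that("a step-function hotspot is covered by the confidence band", {
  # truth: carriers in [1, L/2] have OR 20 against non-carriers, OR 1
  # elsewhere; the fitted curve's 95% CI should cover the truth at most
  # positions
  L <- 500L
  nCase <- 500L
  nCtrl <- 5000L
  cover <- vapply(1:40, function(s) {
    set.seed(7000 + s)
    nCar <- 300L
    pos <- sample.int(L, nCar, replace = TRUE)
    baseOdds <- 0.08
    orTrue <- ifelse(pos <= L / 2, 20, 1)
    pCase <- (baseOdds * orTrue) / (1 + baseOdds * orTrue)
    isCase <- rbinom(nCar, 1, pCase)
    v <- rbind(makeVariants(pos[isCase == 1], "case"),
               makeVariants(pos[isCase == 0], "control"))
    # cohort sizes chosen so the non-carrier case:control odds equal
    # baseOdds, making log(orTrue) the exact carrier-vs-non-carrier truth
    ds <- GeneDataset("step", L,
                      round(nCtrl * baseOdds) + sum(isCase == 1),
                      nCtrl + sum(isCase == 0), v)
    fr <- assembleGamFrame(ds)
    m <- fitHotspot(fr)
    at <- seq(10L, L - 10L, by = 10L)
    pr <- predictPositionOR(m, at)
    truth <- log(ifelse(at <= L / 2, 20, 1))
    mean(log(pr$ci_low) <= truth & truth <= log(pr$ci_high))
  }, numeric(1))
  # pointwise coverage is necessarily poor right at the discontinuity (a
  # smooth cannot jump), which caps attainable coverage around 0.8 here;
  # the band must still cover the truth at the large majority of positions
  expect_gte(mean(cover), 0.75)
})

test_that("point estimates are invariant to weight rescaling at fixed
           penalty", {
  sim <- simulateGene(SimulationScenario("single_cluster"), seed = 42)
  fr <- assembleGamFrame(sim@dataset)
  m1 <- fitHotspot(fr)
  lam <- smoothingParameter(m1)
  cst <- 3.7
  fr2 <- fr
  fr2@frame$weight <- fr2@frame$weight * cst
  # scaled frequency weights are legitimately non-integer
  m2 <- suppressWarnings(fitHotspot(fr2, sp = lam * cst))
  at <- seq(10L, 490L, by = 20L)
  p1 <- predictPositionOR(m1, at)
  p2 <- predictPositionOR(m2, at)
  expect_equal(p2$log_or, p1$log_or, tolerance = 1e-6)
  expect_equal(p2$se, p1$se / sqrt(cst), tolerance = 1e-4)
})

test_that("evidence strata follow the OR thresholds monotonically", {
  expect_equal(as.character(stratifyEvidence(c(1, 4.999, 5, 9.999, 10,
                                               19.99, 20, 99.9, 100,
                                               150))),
               c("none", "none", "weak", "weak", "supporting",
                 "supporting", "moderate", "moderate", "strong",
                 "strong"))
  ors <- sort(runif(50, 0.1, 200))
  ev <- stratifyEvidence(ors)
  expect_true(all(diff(as.integer(ev)) >= 0))
  expect_error(stratifyEvidence(0), "> 0")
})

test_that("probabilities map to odds", {
  expect_equal(probabilityOddsMap(0.5), 1)
  expect_equal(probabilityOddsMap(0.9), 9)
  expect_equal(probabilityOddsMap(0.99), 99)
  expect_error(probabilityOddsMap(1), "inside")
})

test_that("Haldane-corrected empirical ORs match hand computation", {
  even <- empiricalORHaldane(5, 5, 5, 5)
  expect_equal(even[["or"]], 1)
  expect_equal(log(even[["ci_high"]]), -log(even[["ci_low"]]),
               tolerance = 1e-12)
  corr <- empiricalORHaldane(1, 9, 0, 100)
  expect_equal(corr[["or"]], 31.736842, tolerance = 1e-6)
  expect_equal(corr[["ci_low"]], 1.2075, tolerance = 1e-3)
  expect_equal(corr[["ci_high"]], 833.9, tolerance = 1e-3)
  plain <- empiricalORHaldane(2, 8, 1, 99)
  expect_equal(plain[["or"]], 24.75)
  expect_error(empiricalORHaldane(0, 10, 0, 100), "undefined")
})
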