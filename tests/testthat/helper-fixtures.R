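# Small in-code fixtures shared across the suite.

makeVariants <- function(positions, cohort, counts = 1L, af = NA_real_) {
  n <- length(positions)
  data.frame(position = as.integer(positions),
             cohort = rep_len(cohort, n),
             carrier_count = rep_len(as.integer(counts), n),
             popmax_af = rep_len(af, n), stringsAsFactors = FALSE)
}

makeDataset <- function(casePos, ctrlPos, L = 100L, nCase = 1000L,
                        nCtrl = 1000L, caseCounts = 1L, ctrlCounts = 1L,
                        gene = "g", coverageCase = NULL,
                        coverageControl = NULL) {
  v <- rbind(makeVariants(casePos, "case", caseCounts),
             makeVariants(ctrlPos, "control", ctrlCounts))
  GeneDataset(gene, L, nCase, nCtrl, v, coverageCase = coverageCase,
              coverageControl = coverageControl)
}

# Cases concentrated in bins 1-2, controls in bins 3-4 (L = 100, k = 4):
# every cell expectation is 5, the chi-squared statistic is 40 on 3 df.
twoBlockDataset <- function() {
  makeDataset(c(10L, 40L), c(60L, 90L), caseCounts = 10L,
              ctrlCounts = 10L)
}

# Carrier-level logistic-model frame with one informative score column:
# P(case | carrier) = plogis(intercept + gamma * score), positions drawn
# uniformly so the smooth has nothing to explain. Returns the GamFrame
# and the aligned feature matrix.
makeRecoveryFrame <- function(seed, gamma = 1, nCarrier = 400L,
                              L = 500L, nCase = 500L, nCtrl = 5000L,
                              intercept = -1) {
  set.seed(seed)
  pos <- sample.int(L, nCarrier, replace = TRUE)
  x <- rnorm(nCarrier)
  isCase <- rbinom(nCarrier, 1, stats::plogis(intercept + gamma * x))
  v <- rbind(
    makeVariants(pos[isCase == 1], "case"),
    makeVariants(pos[isCase == 0], "control"))
  ds <- GeneDataset("recov", L, nCase, nCtrl, v)
  fr <- assembleGamFrame(ds)
  X <- matrix(c(x[isCase == 1], x[isCase == 0]), ncol = 1,
              dimnames = list(NULL, "feature_01"))
  list(frame = fr, X = X)
}
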