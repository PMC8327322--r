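#' Bias-adjusted Monte-Carlo exceedance rate
#'
#' The (r+1)/(n+1) estimator of a rejection probability from r rejections
#' in n replicates; always strictly inside (0, 1].
#'
#' @param r number of rejections (0 <= r <= n).
#' @param n number of replicates (>= 1).
#' @return the estimate.
#' @examples
#' estimateExceedanceRate(49, 999)  # 0.05
#' @export
estimateExceedanceRate <- function(r, n) {
  stopifnot(n >= 1, r >= 0, r <= n)
  (r + 1) / (n + 1)
}

# Replicate-level seed derived from the master seed: distinct per
# replicate, reproducible, and kept below 2^31.
replicateSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 104729) %% 2147483647)
}

# Named single-dataset tests used by the power harness. Each takes a
# GeneDataset and returns a p-value.
testRegistry <- function() {
  list(
    burden = function(ds) burdenTest(ds)$p.value,
    bin = function(ds) suppressWarnings(binTest(ds))$p.value,
    clusterburden = function(ds) pCombined(suppressWarnings(
      clusterBurden(ds))),
    ad = function(ds) adTest(cohortPositions(ds, "case"),
                             cohortPositions(ds, "control"))$p.value,
    ks = function(ds) suppressWarnings(
      stats::ks.test(cohortPositions(ds, "case"),
                     cohortPositions(ds, "control")))$p.value
  )
}

resolveTests <- function(tests) {
  reg <- testRegistry()
  if (is.function(tests)) return(list(custom = tests))
  stopifnot(all(tests %in% names(reg)))
  reg[tests]
}

#' Monte-Carlo power / type-I-error study
#'
#' Simulates \code{nReps} datasets under a scenario, applies one or more
#' tests to every replicate, and estimates each test's rejection
#' probability at level \code{alpha} with the (r+1)/(n+1) estimator,
#' together with its Monte-Carlo standard error. All tests see the same
#' replicates (paired comparison); the whole study is reproducible from
#' \code{seed}.
#'
#' @param tests character vector naming tests ("burden", "bin",
#'   "clusterburden", "ad", "ks") or a single function
#'   \code{GeneDataset -> p}.
#' @param scenario a \linkS4class{SimulationScenario}.
#' @param nReps number of replicates (>= 100 recommended).
#' @param alpha nominal level (default 0.05).
#' @param seed master seed.
#' @return data.frame with one row per test: test, scenario, n_reps,
#'   alpha, rejections, estimate, mc_se.
#' @export
runPowerStudy <- function(tests, scenario, nReps, alpha = 0.05,
                          seed = 1L) {
  fns <- resolveTests(tests)
  rej <- stats::setNames(numeric(length(fns)), names(fns))
  for (i in seq_len(nReps)) {
    ds <- simulateGene(scenario, seed = replicateSeed(seed, i))@dataset
    for (nm in names(fns)) {
      p <- fns[[nm]](ds)
      if (!is.na(p) && p < alpha) rej[nm] <- rej[nm] + 1
    }
  }
  est <- vapply(rej, estimateExceedanceRate, numeric(1), n = nReps)
  data.frame(test = names(fns), scenario = scenario@name,
             n_reps = as.integer(nReps), alpha = alpha,
             rejections = as.integer(rej), estimate = est,
             mc_se = sqrt(est * (1 - est) / nReps),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Independence diagnostic for the burden and BIN-test p-values
#'
#' Fisher's method assumes its component p-values are independent. This
#' simulates replicates under a scenario, computes the one-sided burden
#' and BIN-test p-values on each, and reports their Spearman rank
#' correlation with its two-sided p-value. Under the null scenario the
#' correlation should be near 0; under disease scenarios the two tests
#' share power through the variant count and correlate positively.
#'
#' @inheritParams runPowerStudy
#' @return list with \code{rho}, \code{p.value}, \code{n_reps} and the
#'   per-replicate p-value matrix \code{pvals}.
#' @export
checkPIndependence <- function(scenario, nReps, seed = 1L) {
  pb <- numeric(nReps)
  pc <- numeric(nReps)
  for (i in seq_len(nReps)) {
    ds <- simulateGene(scenario, seed = replicateSeed(seed, i))@dataset
    pb[i] <- burdenTest(ds)$p.value
    pc[i] <- suppressWarnings(binTest(ds))$p.value
  }
  ct <- suppressWarnings(stats::cor.test(pb, pc, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value,
       n_reps = as.integer(nReps), pvals = cbind(p_burden = pb,
                                                 p_cluster = pc))
}

# Power of a chi-squared LR test with non-centrality ncp at level alpha.
ncpPower <- function(ncp, df, alpha) {
  stats::pchisq(stats::qchisq(1 - alpha, df), df, ncp = ncp,
                lower.tail = FALSE)
}

#' Post hoc sample-size multiplier for burden versus ClusterBurden
#'
#' Treats the burden test and the combined ClusterBurden test as
#' likelihood-ratio tests whose non-centrality parameters scale linearly
#' with sample size: the observed p-values are inverted to chi-squared
#' statistics (1 df for burden, 4 df for the Fisher combination), each
#' statistic is taken as the non-centrality parameter of its test, and
#' the multiplier c solves power(c * ncp_burden, 1 df) =
#' power(ncp_combined, 4 df) at level \code{alpha}. c is the factor by
#' which the sample size would have to grow for the burden-alone test to
#' match ClusterBurden's power; the multiplier is 1 when the burden test
#' is already at least as powerful.
#'
#' @param pBurden,pCombined observed p-values in (0, 1).
#' @param alpha nominal level (default 0.05).
#' @param dfBurden,dfCombined reference-distribution degrees of freedom
#'   (defaults 1 and 4).
#' @return list with \code{multiplier}, \code{percent_increase},
#'   \code{ncp_burden}, \code{ncp_combined}, \code{power_burden},
#'   \code{power_combined}, \code{residual} (root-finder residual) and
#'   \code{unbounded} (TRUE when no multiplier below 1e4 suffices).
#' @export
posthocMultiplier <- function(pBurden, pCombined, alpha = 0.05,
                              dfBurden = 1, dfCombined = 4) {
  stopifnot(pBurden > 0, pBurden < 1, pCombined > 0, pCombined < 1)
  ncpB <- stats::qchisq(pBurden, dfBurden, lower.tail = FALSE)
  ncpC <- stats::qchisq(pCombined, dfCombined, lower.tail = FALSE)
  powB <- ncpPower(ncpB, dfBurden, alpha)
  powC <- ncpPower(ncpC, dfCombined, alpha)
  out <- list(ncp_burden = ncpB, ncp_combined = ncpC,
              power_burden = powB, power_combined = powC)
  if (powB >= powC) {
    return(c(out, list(multiplier = 1, percent_increase = 0,
                       residual = 0, unbounded = FALSE)))
  }
  f <- function(cc) ncpPower(cc * ncpB, dfBurden, alpha) - powC
  if (f(1e4) < 0) {
    return(c(out, list(multiplier = NA_real_,
                       percent_increase = NA_real_, residual = NA_real_,
                       unbounded = TRUE)))
  }
  root <- stats::uniroot(f, c(1, 1e4), tol = 1e-12)
  c(out, list(multiplier = root$root,
              percent_increase = 100 * (root$root - 1),
              residual = abs(f(root$root)), unbounded = FALSE))
}
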