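#' One-sided burden test for carrier excess in cases
#'
#' Fisher's exact test (hypergeometric upper tail) on the 2 x 2 table of
#' rare-variant carriers and non-carriers, testing only for enrichment in
#' the case cohort: protective rare-variant burdens are not part of the
#' alternative. With \code{useCoverage = TRUE} and coverage profiles
#' present, the effective cohort sizes are the nominal sizes scaled by the
#' gene-wide mean 10x coverage (rounded).
#'
#' @param ds a \linkS4class{GeneDataset}.
#' @param useCoverage adjust cohort sizes by gene-wide mean coverage.
#' @param distinct count each variant record once instead of once per
#'   carrier.
#' @return list with \code{p.value}, the 2 x 2 \code{table} (carriers /
#'   non-carriers by cohort) and the effective cohort sizes.
#' @examples
#' v <- data.frame(position = 1:5, cohort = "case", carrier_count = 1L,
#'                 popmax_af = NA_real_)
#' ds <- GeneDataset("g", 100L, 10L, 10L, v)
#' burdenTest(ds)$p.value  # choose(10,5)/choose(20,5) = 0.01625...
#' @export
burdenTest <- function(ds, useCoverage = FALSE, distinct = FALSE) {
  v <- ds@variants
  count1 <- function(cohort) {
    w <- v$cohort == cohort
    if (distinct) sum(w) else sum(v$carrier_count[w])
  }
  a <- count1("case")
  c_ <- count1("control")
  nCase <- ds@nCases
  nCtrl <- ds@nControls
  if (useCoverage) {
    if (!is.null(ds@coverageCase))
      nCase <- as.integer(round(nCase * mean(ds@coverageCase)))
    if (!is.null(ds@coverageControl))
      nCtrl <- as.integer(round(nCtrl * mean(ds@coverageControl)))
  }
  if (a > nCase || c_ > nCtrl)
    stop("carriers exceed the (effective) cohort size")
  # Upper tail of the hypergeometric: P(case carriers >= a) given margins.
  p <- stats::phyper(a - 1, a + c_, nCase + nCtrl - a - c_, nCase,
                     lower.tail = FALSE)
  tab <- matrix(c(a, nCase - a, c_, nCtrl - c_), nrow = 2,
                dimnames = list(c("carrier", "noncarrier"),
                                c("case", "control")))
  list(p.value = min(1, p), table = tab,
       nCasesEffective = nCase, nControlsEffective = nCtrl)
}

#' Combine two p-values by Fisher's method
#'
#' X = -2(log p1 + log p2) is referred to the chi-squared distribution
#' with 4 degrees of freedom, whose upper tail has the closed form
#' exp(-X/2) (1 + X/2). Inputs are floored at 1e-300 before taking logs to
#' avoid overflow. Valid only when the two component tests are
#' independent.
#'
#' @param p1,p2 p-values in (0, 1].
#' @return the combined p-value.
#' @examples
#' fishersMethod(1, 1)        # 1
#' fishersMethod(0.05, 0.05)  # 0.01747...
#' @export
fishersMethod <- function(p1, p2) {
  for (p in c(p1, p2))
    if (!is.finite(p) || p <= 0 || p > 1)
      stop("p-values must lie in (0, 1]")
  p1 <- max(p1, 1e-300)
  p2 <- max(p2, 1e-300)
  X <- -2 * (log(p1) + log(p2))
  min(1, exp(-X / 2) * (1 + X / 2))
}

#' ClusterBurden: joint burden and clustering association test
#'
#' Runs the one-sided burden test and the BIN-test on the same gene and
#' combines their p-values with Fisher's method, testing the joint
#' hypothesis of an excess of rare missense variants in cases and
#' differential positional clustering. When the BIN-test is degenerate
#' (too few informative bins) the combined p-value falls back to the
#' burden p-value and the result is flagged.
#'
#' @inheritParams burdenTest
#' @return a \linkS4class{TestResult}.
#' @examples
#' v <- data.frame(position = c(rep(20L, 6), 150L, 400L),
#'                 cohort = c(rep("case", 6), "control", "control"),
#'                 carrier_count = c(rep(2L, 6), 5L, 5L),
#'                 popmax_af = NA_real_)
#' ds <- GeneDataset("MYH7", 500L, 500L, 5000L, v)
#' clusterBurden(ds)
#' @export
clusterBurden <- function(ds, useCoverage = FALSE, distinct = FALSE) {
  v <- ds@variants
  pb <- burdenTest(ds, useCoverage = useCoverage,
                   distinct = distinct)$p.value
  bt <- withCallingHandlers(
    binTest(ds, useCoverage = useCoverage, distinct = distinct),
    warning = function(w) invokeRestart("muffleWarning"))
  pcl <- bt$p.value
  pc <- if (bt$degenerate) pb else fishersMethod(pb, pcl)
  new("TestResult", gene = ds@gene, pBurden = pb, pCluster = pcl,
      pCombined = pc, statCluster = bt$statistic,
      dfCluster = as.integer(bt$df),
      nCaseVariants = sum(v$cohort == "case"),
      nControlVariants = sum(v$cohort == "control"),
      degenerate = bt$degenerate)
}

#' @describeIn TestResult-class one-sided burden p-value.
#' @export
setMethod("pBurden", "TestResult", function(x) x@pBurden)

#' @describeIn TestResult-class BIN-test p-value.
#' @export
setMethod("pCluster", "TestResult", function(x) x@pCluster)

#' @describeIn TestResult-class ClusterBurden combined p-value.
#' @export
setMethod("pCombined", "TestResult", function(x) x@pCombined)

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: %s (%d case / %d control variant records)\n",
              object@gene, object@nCaseVariants, object@nControlVariants))
  cat(sprintf("  burden (one-sided)   p = %.4g\n", object@pBurden))
  cat(sprintf("  BIN-test             p = %.4g  (X2 = %.3f, df = %d)%s\n",
              object@pCluster, object@statCluster, object@dfCluster,
              if (object@degenerate) " [degenerate]" else ""))
  cat(sprintf("  ClusterBurden        p = %.4g\n", object@pCombined))
})

#' @export
#' @method as.data.frame TestResult
as.data.frame.TestResult <- function(x, ...) {
  data.frame(gene = x@gene, n_case_variants = x@nCaseVariants,
             n_control_variants = x@nControlVariants,
             p_burden = x@pBurden, p_cluster = x@pCluster,
             p_combined = x@pCombined, stat_cluster = x@statCluster,
             df_cluster = x@dfCluster, degenerate = x@degenerate,
             stringsAsFactors = FALSE)
}
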