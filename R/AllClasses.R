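#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GeneDataset: case-control rare-variant data for one gene
#'
#' Container for all observed rare missense variants of a single gene in a
#' case-control study, together with cohort sizes, the protein length and
#' optional per-residue sequencing-coverage profiles. Residue positions are
#' 1-based amino-acid indices. A variant observed in both cohorts appears as
#' two rows with cohort-specific carrier counts; nothing links them.
#'
#' The \code{variants} slot is a data.frame with required columns
#' \code{position} (integer, 1-based), \code{cohort} (\code{"case"} or
#' \code{"control"}), \code{carrier_count} (integer >= 1) and
#' \code{popmax_af} (numeric in [0,1], \code{NA} for variants absent from
#' the reference population). Additional numeric columns are treated as
#' in-silico predictor scores; an optional \code{label} column carries
#' expert ACMG-style classifications.
#'
#' @slot gene gene symbol.
#' @slot proteinLength protein length L in residues.
#' @slot nCases,nControls cohort sizes.
#' @slot variants variant table (see Details).
#' @slot coverageCase,coverageControl optional length-L vectors of the mean
#'   proportion of samples with >= 10x depth at each residue, in (0, 1].
#'
#' @aliases GeneDataset
#' @exportClass GeneDataset
setClass("GeneDataset",
  representation(
    gene = "character",
    proteinLength = "integer",
    nCases = "integer",
    nControls = "integer",
    variants = "data.frame",
    coverageCase = "numericOrNULL",
    coverageControl = "numericOrNULL"
  )
)

setValidity("GeneDataset", function(object) {
  msg <- character(0)
  v <- object@variants
  L <- object@proteinLength
  req <- c("position", "cohort", "carrier_count", "popmax_af")
  if (!all(req %in% names(v))) {
    return(paste("variants is missing column(s):",
                 paste(setdiff(req, names(v)), collapse = ", ")))
  }
  if (length(object@gene) != 1L || is.na(object@gene))
    msg <- c(msg, "gene must be a single symbol")
  if (L < 1L) msg <- c(msg, "proteinLength must be positive")
  if (object@nCases < 1L || object@nControls < 1L)
    msg <- c(msg, "cohort sizes must be positive")
  if (nrow(v)) {
    if (!all(v$cohort %in% c("case", "control")))
      msg <- c(msg, "cohort must be 'case' or 'control'")
    if (any(v$position < 1L | v$position > L))
      msg <- c(msg, "variant positions must lie in [1, proteinLength]")
    if (any(v$carrier_count < 1L))
      msg <- c(msg, "carrier_count must be >= 1")
    af <- v$popmax_af
    if (any(!is.na(af) & (af < 0 | af > 1)))
      msg <- c(msg, "popmax_af must be in [0, 1] or NA")
    for (ch in c("case", "control")) {
      tot <- sum(v$carrier_count[v$cohort == ch])
      N <- if (ch == "case") object@nCases else object@nControls
      if (tot > N)
        msg <- c(msg, sprintf("%s carriers (%d) exceed cohort size (%d)",
                              ch, tot, N))
    }
  }
  for (sl in c("coverageCase", "coverageControl")) {
    cv <- slot(object, sl)
    if (!is.null(cv)) {
      if (length(cv) != L)
        msg <- c(msg, sprintf("%s must have length proteinLength", sl))
      if (any(is.na(cv) | cv <= 0 | cv > 1))
        msg <- c(msg, sprintf("%s values must lie in (0, 1]", sl))
    }
  }
  if (length(msg)) msg else TRUE
})

#' BinTable: binned positional counts for one gene
#'
#' A k x 2 table of variant counts per equal-length positional bin, one
#' column per cohort. Counts are real-valued when coverage-adjusted. Bins
#' are half-open \code{[lo, hi)} except the last, which is closed.
#'
#' @slot k number of bins.
#' @slot edges k+1 strictly increasing bin boundaries covering [1, L].
#' @slot countsCase,countsControl per-bin counts.
#' @slot adjusted TRUE when counts are coverage-adjusted.
#' @exportClass BinTable
setClass("BinTable",
  representation(k = "integer", edges = "numeric",
                 countsCase = "numeric", countsControl = "numeric",
                 adjusted = "logical")
)

setValidity("BinTable", function(object) {
  msg <- character(0)
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (length(object@edges) != object@k + 1L)
    msg <- c(msg, "edges must have length k+1")
  if (any(diff(object@edges) <= 0))
    msg <- c(msg, "edges must be strictly increasing")
  if (length(object@countsCase) != object@k ||
      length(object@countsControl) != object@k)
    msg <- c(msg, "count vectors must have length k")
  if (any(object@countsCase < 0) || any(object@countsControl < 0))
    msg <- c(msg, "counts must be non-negative")
  if (!object@adjusted &&
      (any(object@countsCase != round(object@countsCase)) ||
       any(object@countsControl != round(object@countsControl))))
    msg <- c(msg, "unadjusted counts must be integers")
  if (length(msg)) msg else TRUE
})

#' TestResult: association-test p-values for one gene
#'
#' Holds the one-sided burden p-value, the BIN-test (clustering) p-value,
#' their Fisher's-method combination (ClusterBurden) and the BIN-test
#' chi-squared statistic with its degrees of freedom.
#'
#' @slot gene gene symbol.
#' @slot pBurden,pCluster,pCombined p-values in (0, 1] (NA when undefined).
#' @slot statCluster BIN-test chi-squared statistic.
#' @slot dfCluster BIN-test degrees of freedom (retained bins minus 1).
#' @slot nCaseVariants,nControlVariants numbers of variant records.
#' @slot degenerate TRUE when the BIN-test was degenerate (fewer than two
#'   bins with nonzero combined counts), in which case \code{pCombined}
#'   falls back to \code{pBurden}.
#' @exportClass TestResult
setClass("TestResult",
  representation(gene = "character",
                 pBurden = "numeric", pCluster = "numeric",
                 pCombined = "numeric",
                 statCluster = "numeric", dfCluster = "integer",
                 nCaseVariants = "integer", nControlVariants = "integer",
                 degenerate = "logical")
)

#' PanelScan: multi-gene panel scan with Bonferroni control
#'
#' @slot results one row per gene: gene, variant counts, the three
#'   p-values and their significance calls.
#' @slot alphaFamily family-wise error rate (default 0.05).
#' @slot nTests number of tests, 3 x number of genes.
#' @slot alphaPerTest Bonferroni threshold alphaFamily / nTests.
#' @exportClass PanelScan
setClass("PanelScan",
  representation(results = "data.frame", alphaFamily = "numeric",
                 nTests = "integer", alphaPerTest = "numeric")
)

setValidity("PanelScan", function(object) {
  if (abs(object@alphaPerTest - object@alphaFamily / object@nTests) > 1e-12)
    "alphaPerTest must equal alphaFamily / nTests" else TRUE
})

#' SimulationScenario: generative parameters for one synthetic experiment
#'
#' Defines a synthetic case-control rare-missense-variant experiment:
#' benign background variation at a per-individual carrier rate with an
#' ultra-rare log-uniform allele-frequency spectrum, plus (outside the null
#' scenario) pathogenic variants whose positions are drawn uniformly over
#' discrete high-risk windows and whose case:control carriage odds equal
#' \code{penetranceOR} (incomplete penetrance: pathogenic variants do occur
#' in controls).
#'
#' @slot name one of "null", "uniform", "single_cluster", "multi_cluster".
#' @slot L protein length (residues).
#' @slot nCases,nControls cohort sizes.
#' @slot clusterWindows 2-column matrix of (start, end) residue windows;
#'   zero rows for the null and uniform scenarios.
#' @slot benignCarrierRate expected benign rare-variant carriers per
#'   individual.
#' @slot pathogenicCarrierFraction fraction of cases carrying a pathogenic
#'   variant.
#' @slot penetranceOR case:control carriage odds ratio of pathogenic
#'   variants.
#' @slot mafThreshold rare-variant allele-frequency filter threshold.
#' @exportClass SimulationScenario
setClass("SimulationScenario",
  representation(name = "character", L = "integer",
                 nCases = "integer", nControls = "integer",
                 clusterWindows = "matrix",
                 benignCarrierRate = "numeric",
                 pathogenicCarrierFraction = "numeric",
                 penetranceOR = "numeric", mafThreshold = "numeric")
)

setValidity("SimulationScenario", function(object) {
  msg <- character(0)
  if (!object@name %in% c("null", "uniform", "single_cluster",
                          "multi_cluster"))
    msg <- c(msg, "unknown scenario name")
  w <- object@clusterWindows
  if (ncol(w) != 2L) msg <- c(msg, "clusterWindows must have 2 columns")
  if (object@name %in% c("null", "uniform")) {
    if (nrow(w) != 0L)
      msg <- c(msg, "null/uniform scenarios must have no cluster windows")
  } else {
    if (nrow(w) == 0L)
      msg <- c(msg, "cluster scenarios need at least one window")
  }
  if (nrow(w)) {
    if (any(w[, 1] < 1) || any(w[, 2] > object@L) || any(w[, 1] > w[, 2]))
      msg <- c(msg, "cluster windows must lie within [1, L]")
    o <- order(w[, 1])
    if (nrow(w) > 1L && any(w[o, 1][-1] <= w[o, 2][-nrow(w)]))
      msg <- c(msg, "cluster windows must not overlap")
  }
  if (object@benignCarrierRate < 0 || object@benignCarrierRate > 1)
    msg <- c(msg, "benignCarrierRate must be in [0, 1]")
  if (object@pathogenicCarrierFraction < 0 ||
      object@pathogenicCarrierFraction >= 1)
    msg <- c(msg, "pathogenicCarrierFraction must be in [0, 1)")
  if (object@penetranceOR <= 0) msg <- c(msg, "penetranceOR must be > 0")
  if (object@mafThreshold <= 0 || object@mafThreshold >= 1)
    msg <- c(msg, "mafThreshold must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' SimulatedDataset: a simulated GeneDataset plus ground truth
#'
#' @slot dataset the simulated \linkS4class{GeneDataset} (after the
#'   allele-frequency filter).
#' @slot truth per-variant data.frame aligned with the variant table:
#'   \code{pathogenic} flag and \code{true_or}.
#' @slot scenario the generating \linkS4class{SimulationScenario}.
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(dataset = "GeneDataset", truth = "data.frame",
                 scenario = "SimulationScenario")
)

#' GamFrame: model frame for the hotspot GAM
#'
#' One row per carrier (expanded to carrier multiplicity) with the
#' case/control response, residue position and a coverage weight, plus
#' exactly two aggregated non-carrier rows (one per cohort) whose weights
#' are the non-carrier counts times the reciprocal gene-wide mean coverage.
#' Non-carrier rows have position 0; the position smooth is nested within
#' carrier status so it is identically zero for them.
#'
#' @slot frame the model frame (columns \code{is_case}, \code{carrier},
#'   \code{carrierO}, \code{position}, \code{weight}, \code{variant_row}).
#' @slot gene,L gene symbol and protein length.
#' @slot coverageWindow half-width (residues) of the window used for
#'   carrier coverage weights.
#' @exportClass GamFrame
setClass("GamFrame",
  representation(frame = "data.frame", gene = "character", L = "integer",
                 coverageWindow = "integer")
)

setValidity("GamFrame", function(object) {
  fr <- object@frame
  msg <- character(0)
  if (sum(fr$carrier == 0) != 2L)
    msg <- c(msg, "frame must contain exactly two aggregated non-carrier rows")
  if (any(fr$weight <= 0)) msg <- c(msg, "weights must be positive")
  if (any(fr$position[fr$carrier == 0] != 0))
    msg <- c(msg, "non-carrier rows must have position 0")
  if (length(msg)) msg else TRUE
})

#' HotspotModel: fitted penalized-spline hotspot (or hotspot+) GAM
#'
#' Wraps the fitted binomial GAM \code{P(case) = b0 + b1 carrier +
#' s(position, by = carrier)} (plus optional linear in-silico feature terms
#' nested within carrier status for hotspot+ models), together with the
#' bookkeeping needed for per-position and per-variant odds-ratio
#' prediction.
#'
#' @slot fit the underlying \code{mgcv::gam} fit.
#' @slot gene,L gene symbol and protein length.
#' @slot basisDim spline basis dimension.
#' @slot smoothing smoothing-parameter criterion ("REML" or "GCV").
#' @slot features selected in-silico feature names (empty for plain
#'   hotspot models).
#' @slot featureMeans training means used to centre feature columns (and
#'   to mean-impute missing scores at prediction time).
#' @exportClass HotspotModel
setClass("HotspotModel",
  representation(fit = "ANY", gene = "character", L = "integer",
                 basisDim = "integer", smoothing = "character",
                 features = "character", featureMeans = "numeric")
)
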