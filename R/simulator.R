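#' Construct a SimulationScenario
#'
#' Describes one synthetic case-control experiment. The default cluster
#' windows, expressed as fractions of the protein length, are
#' \code{[0.20 L, 0.35 L]} for \code{single_cluster} and
#' \code{[0.10, 0.20] + [0.50, 0.60] + [0.80, 0.90] L} for
#' \code{multi_cluster}. See \linkS4class{SimulationScenario} for the
#' meaning of the rate parameters; the defaults (benign carrier rate 0.06
#' per individual, pathogenic case-carrier fraction 0.2, penetrance odds
#' ratio 50) are repository defaults describing a strongly penetrant
#' Mendelian disease gene.
#'
#' @param name scenario name: "null", "uniform", "single_cluster" or
#'   "multi_cluster".
#' @param L protein length in residues.
#' @param nCases,nControls cohort sizes (desk-scale defaults 500 / 5000).
#' @param clusterWindows optional 2-column matrix of residue windows;
#'   defaults depend on \code{name}.
#' @param benignCarrierRate expected benign rare-variant carriers per
#'   individual.
#' @param pathogenicCarrierFraction fraction of cases carrying a
#'   pathogenic variant (0 for the null scenario).
#' @param penetranceOR case:control carriage odds ratio of pathogenic
#'   variants.
#' @param mafThreshold allele-frequency filter threshold.
#' @return a \linkS4class{SimulationScenario}.
#' @export
SimulationScenario <- function(name = c("null", "uniform", "single_cluster",
                                        "multi_cluster"),
                               L = 500L, nCases = 500L, nControls = 5000L,
                               clusterWindows = NULL,
                               benignCarrierRate = 0.06,
                               pathogenicCarrierFraction = if
                                 (name[1] == "null") 0 else 0.2,
                               penetranceOR = 50,
                               mafThreshold = 1e-4) {
  name <- match.arg(name)
  L <- as.integer(L)
  if (is.null(clusterWindows)) {
    frac <- switch(name,
      null = ,
      uniform = matrix(numeric(0), ncol = 2),
      single_cluster = matrix(c(0.20, 0.35), ncol = 2),
      multi_cluster = matrix(c(0.10, 0.20, 0.50, 0.60, 0.80, 0.90),
                             ncol = 2, byrow = TRUE))
    clusterWindows <- round(frac * L)
  }
  clusterWindows <- matrix(as.numeric(clusterWindows), ncol = 2)
  new("SimulationScenario", name = name, L = L,
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      clusterWindows = clusterWindows,
      benignCarrierRate = benignCarrierRate,
      pathogenicCarrierFraction = pathogenicCarrierFraction,
      penetranceOR = penetranceOR, mafThreshold = mafThreshold)
}

#' @describeIn SimulationScenario-class scenario name.
#' @export
setMethod("scenarioName", "SimulationScenario", function(x) x@name)

#' @describeIn SimulationScenario-class cluster-window matrix.
#' @export
setMethod("clusterWindows", "SimulationScenario",
          function(x) x@clusterWindows)

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf("SimulationScenario: %s (L = %d, %d cases / %d controls)\n",
              object@name, object@L, object@nCases, object@nControls))
  cat(sprintf(
    "  benign rate %.3g, pathogenic case fraction %.3g, OR %.3g, MAF < %g\n",
    object@benignCarrierRate, object@pathogenicCarrierFraction,
    object@penetranceOR, object@mafThreshold))
  if (nrow(object@clusterWindows))
    cat("  windows:",
        paste(sprintf("[%d, %d]", object@clusterWindows[, 1],
                      object@clusterWindows[, 2]), collapse = " "), "\n")
})

# Draw positions uniformly over the scenario's high-risk windows (or the
# whole protein for the uniform scenario).
drawPathogenicPositions <- function(scenario, n) {
  if (n == 0L) return(integer(0))
  w <- scenario@clusterWindows
  if (!nrow(w)) return(sample.int(scenario@L, n, replace = TRUE))
  sizes <- w[, 2] - w[, 1] + 1
  win <- sample.int(nrow(w), n, replace = TRUE, prob = sizes)
  as.integer(w[win, 1] + floor(stats::runif(n) * sizes[win]))
}

# Aggregate per-carrier positions into distinct variant records with a
# drawn population AF. afRange gives the log10-uniform AF spectrum.
aggregateVariants <- function(positions, cohort, afRange) {
  if (!length(positions)) {
    out <- emptyVariantTable()
    return(out)
  }
  tab <- table(positions)
  n <- length(tab)
  data.frame(position = as.integer(names(tab)),
             cohort = cohort,
             carrier_count = as.integer(tab),
             popmax_af = 10^stats::runif(n, afRange[1], afRange[2]),
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic case-control gene dataset
#'
#' Generates one gene's worth of case-control rare missense variants under
#' the given scenario: (1) every individual carries a benign rare variant
#' with probability \code{benignCarrierRate}, at a position uniform on
#' [1, L], and each distinct benign variant receives a population AF drawn
#' log10-uniform on [-6.5, -3.5]; (2) outside the null scenario,
#' pathogenic carriers are drawn so that the case:control carriage odds
#' equal \code{penetranceOR} (incomplete penetrance: pathogenic variants
#' do occur in controls), with positions uniform over the scenario's
#' high-risk windows and population AFs log10-uniform on [-7, -4.5]; (3)
#' variants whose drawn AF reaches \code{mafThreshold} are filtered out of
#' both cohorts; (4) ground-truth pathogenicity labels are recorded.
#'
#' @param scenario a \linkS4class{SimulationScenario}.
#' @param seed optional integer seed; equal seeds yield identical
#'   datasets.
#' @return a \linkS4class{SimulatedDataset}.
#' @examples
#' sc <- SimulationScenario("single_cluster", L = 500L)
#' sim <- simulateGene(sc, seed = 7)
#' sim
#' @export
simulateGene <- function(scenario, seed = NULL) {
  stopifnot(is(scenario, "SimulationScenario"))
  if (!is.null(seed)) set.seed(seed)
  L <- scenario@L
  nCase <- scenario@nCases
  nCtrl <- scenario@nControls
  pc <- scenario@pathogenicCarrierFraction
  if (scenario@name == "null" && pc > 0)
    stop("the null scenario must have pathogenicCarrierFraction = 0")
  # benign background, identical mechanism in both cohorts
  nbCase <- stats::rbinom(1, nCase, scenario@benignCarrierRate)
  nbCtrl <- stats::rbinom(1, nCtrl, scenario@benignCarrierRate)
  ben <- rbind(
    aggregateVariants(sample.int(L, nbCase, replace = TRUE), "case",
                      c(-6.5, -3.5)),
    aggregateVariants(sample.int(L, nbCtrl, replace = TRUE), "control",
                      c(-6.5, -3.5)))
  ben$pathogenic <- rep(FALSE, nrow(ben))
  # pathogenic variants with incomplete penetrance
  if (pc > 0) {
    oddsCase <- pc / (1 - pc)
    oddsCtrl <- oddsCase / scenario@penetranceOR
    pCtrl <- oddsCtrl / (1 + oddsCtrl)
    npCase <- stats::rbinom(1, nCase, pc)
    npCtrl <- stats::rbinom(1, nCtrl, pCtrl)
    pat <- rbind(
      aggregateVariants(drawPathogenicPositions(scenario, npCase), "case",
                        c(-7, -4.5)),
      aggregateVariants(drawPathogenicPositions(scenario, npCtrl),
                        "control", c(-7, -4.5)))
    pat$pathogenic <- rep(TRUE, nrow(pat))
  } else {
    pat <- NULL
  }
  v <- if (is.null(pat)) ben else rbind(ben, pat)
  if (sum(v$carrier_count[v$cohort == "case"]) > nCase ||
      sum(v$carrier_count[v$cohort == "control"]) > nCtrl)
    stop("simulated carrier counts exceed the cohort size; reduce the ",
         "carrier rates")
  v <- v[order(v$cohort, v$position, v$pathogenic), , drop = FALSE]
  keep <- v$popmax_af < scenario@mafThreshold
  v <- v[keep, , drop = FALSE]
  rownames(v) <- NULL
  truth <- data.frame(cohort = v$cohort, position = v$position,
                      pathogenic = v$pathogenic,
                      true_or = ifelse(v$pathogenic, scenario@penetranceOR,
                                       1),
                      stringsAsFactors = FALSE)
  v$pathogenic <- NULL
  ds <- GeneDataset(gene = sprintf("sim_%s", scenario@name),
                    proteinLength = L, nCases = nCase, nControls = nCtrl,
                    variants = v)
  new("SimulatedDataset", dataset = ds, truth = truth, scenario = scenario)
}

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset (%s): %d variant records, %d pathogenic\n",
              object@scenario@name, nrow(object@truth),
              sum(object@truth$pathogenic)))
  show(object@dataset)
})

#' The standard simulation-study scenarios
#'
#' Returns the six alternative scenarios of the simulation study (three
#' clustering patterns x two protein lengths) plus one null scenario per
#' length, at full scale (5000 cases / 125000 controls), together with
#' desk-scale counterparts (500 cases / 5000 controls) suitable for
#' interactive use and calibration runs.
#'
#' @return named list of \linkS4class{SimulationScenario} objects; names
#'   are \code{<scale>_<name>_L<length>}.
#' @export
defaultScenarios <- function() {
  out <- list()
  for (scale in c("full", "desk")) {
    nCase <- if (scale == "full") 5000L else 500L
    nCtrl <- if (scale == "full") 125000L else 5000L
    for (L in c(500L, 1000L)) {
      for (nm in c("null", "uniform", "single_cluster", "multi_cluster")) {
        out[[sprintf("%s_%s_L%d", scale, nm, L)]] <-
          SimulationScenario(nm, L = L, nCases = nCase, nControls = nCtrl)
      }
    }
  }
  out
}

#' Scenarios for comparing test power
#'
#' The four clustered desk-scale scenarios (single and multiple clusters,
#' protein lengths 500 and 1000) parameterized at a mid-range operating
#' point (pathogenic case-carrier fraction 0.03, penetrance odds ratio
#' 10). Power comparisons between tests are only informative away from
#' the floor and the ceiling; at the strongly penetrant repository
#' defaults every test rejects essentially always, so rankings would be
#' undecidable. See the methods vignette for the design rationale.
#'
#' @return named list of \linkS4class{SimulationScenario} objects.
#' @export
powerStudyScenarios <- function() {
  out <- list()
  for (L in c(500L, 1000L)) {
    for (nm in c("single_cluster", "multi_cluster")) {
      out[[sprintf("%s_L%d", nm, L)]] <-
        SimulationScenario(nm, L = L, nCases = 500L, nControls = 5000L,
                           pathogenicCarrierFraction = 0.03,
                           penetranceOR = 10)
    }
  }
  out
}
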