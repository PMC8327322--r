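#' @rdname GeneDataset-class
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))

#' @rdname GeneDataset-class
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))

#' @rdname GeneDataset-class
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname GeneDataset-class
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname GeneDataset-class
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname GeneDataset-class
#' @export
setGeneric("coverageProfile",
           function(x, cohort = c("case", "control"))
             standardGeneric("coverageProfile"))

#' Filter variants to the ultra-rare stratum
#'
#' Keeps variants whose reference-population maximum allele frequency
#' (popmax AF) lies strictly below \code{afThreshold}. Variants with a
#' missing popmax AF are retained: absence from the reference population is
#' the strongest rarity evidence. Input order is preserved and the
#' operation is idempotent.
#'
#' @param x a \linkS4class{GeneDataset} or a variant data.frame with a
#'   \code{popmax_af} column.
#' @param afThreshold strict upper AF bound, in (0, 1); default 1e-4.
#' @return an object of the same class with only the retained variants.
#' @examples
#' v <- data.frame(position = 1:3, cohort = "case", carrier_count = 1,
#'                 popmax_af = c(5e-5, 1e-4, 0.5))
#' filterRare(v)  # keeps only the first row (strict inequality)
#' @export
setGeneric("filterRare",
           function(x, afThreshold = 1e-4) standardGeneric("filterRare"))

#' @rdname carrierSummary
#' @export
setGeneric("carrierSummary", function(x) standardGeneric("carrierSummary"))

#' @rdname TestResult-class
#' @export
setGeneric("pBurden", function(x) standardGeneric("pBurden"))

#' @rdname TestResult-class
#' @export
setGeneric("pCluster", function(x) standardGeneric("pCluster"))

#' @rdname TestResult-class
#' @export
setGeneric("pCombined", function(x) standardGeneric("pCombined"))

#' @rdname PanelScan-class
#' @export
setGeneric("panelResults", function(x) standardGeneric("panelResults"))

#' @rdname PanelScan-class
#' @export
setGeneric("alphaPerTest", function(x) standardGeneric("alphaPerTest"))

#' @rdname SimulationScenario-class
#' @export
setGeneric("scenarioName", function(x) standardGeneric("scenarioName"))

#' @rdname SimulationScenario-class
#' @export
setGeneric("clusterWindows", function(x) standardGeneric("clusterWindows"))

#' @rdname HotspotModel-class
#' @export
setGeneric("modelEDF", function(x) standardGeneric("modelEDF"))

#' @rdname HotspotModel-class
#' @export
setGeneric("smoothingParameter",
           function(x) standardGeneric("smoothingParameter"))

#' @rdname HotspotModel-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
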