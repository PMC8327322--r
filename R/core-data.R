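#' Construct a GeneDataset
#'
#' @param gene gene symbol.
#' @param proteinLength protein length in residues.
#' @param nCases,nControls cohort sizes.
#' @param variants data.frame with columns \code{position}, \code{cohort},
#'   \code{carrier_count}, \code{popmax_af}; extra numeric columns are
#'   carried along as in-silico scores.
#' @param coverageCase,coverageControl optional per-residue vectors (length
#'   \code{proteinLength}) of the mean proportion of samples with >= 10x
#'   depth, in (0, 1].
#' @return a \linkS4class{GeneDataset}.
#' @seealso \code{\link{filterRare}}, \code{\link{carrierSummary}},
#'   \code{\link{clusterBurden}}
#' @examples
#' v <- data.frame(position = c(10L, 40L), cohort = c("case", "control"),
#'                 carrier_count = c(2L, 1L), popmax_af = c(NA, 2e-5))
#' GeneDataset("TNNI3", 210L, nCases = 100L, nControls = 1000L, variants = v)
#' @export
GeneDataset <- function(gene, proteinLength, nCases, nControls,
                        variants = emptyVariantTable(),
                        coverageCase = NULL, coverageControl = NULL) {
  variants <- as.data.frame(variants)
  if (nrow(variants)) {
    variants$position <- as.integer(variants$position)
    variants$carrier_count <- as.integer(variants$carrier_count)
    variants$cohort <- as.character(variants$cohort)
    variants$popmax_af <- as.numeric(variants$popmax_af)
  }
  rownames(variants) <- NULL
  new("GeneDataset", gene = as.character(gene),
      proteinLength = as.integer(proteinLength),
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      variants = variants,
      coverageCase = if (is.null(coverageCase)) NULL else
        as.numeric(coverageCase),
      coverageControl = if (is.null(coverageControl)) NULL else
        as.numeric(coverageControl))
}

emptyVariantTable <- function() {
  data.frame(position = integer(0), cohort = character(0),
             carrier_count = integer(0), popmax_af = numeric(0))
}

#' @describeIn GeneDataset gene symbol.
#' @export
setMethod("geneSymbol", "GeneDataset", function(x) x@gene)

#' @describeIn GeneDataset protein length L (residues).
#' @export
setMethod("proteinLength", "GeneDataset", function(x) x@proteinLength)

#' @describeIn GeneDataset number of cases.
#' @export
setMethod("nCases", "GeneDataset", function(x) x@nCases)

#' @describeIn GeneDataset number of controls.
#' @export
setMethod("nControls", "GeneDataset", function(x) x@nControls)

#' @describeIn GeneDataset the variant data.frame.
#' @export
setMethod("variantTable", "GeneDataset", function(x) x@variants)

#' @describeIn GeneDataset per-residue coverage profile for one cohort
#'   (NULL when absent).
#' @export
setMethod("coverageProfile", "GeneDataset", function(x, cohort) {
  cohort <- match.arg(cohort, c("case", "control"))
  if (cohort == "case") x@coverageCase else x@coverageControl
})

setMethod("show", "GeneDataset", function(object) {
  v <- object@variants
  cat(sprintf("GeneDataset: %s (L = %d)\n", object@gene,
              object@proteinLength))
  cat(sprintf("  %d cases, %d controls\n", object@nCases, object@nControls))
  cat(sprintf("  %d case / %d control variant records (%d / %d carriers)\n",
              sum(v$cohort == "case"), sum(v$cohort == "control"),
              sum(v$carrier_count[v$cohort == "case"]),
              sum(v$carrier_count[v$cohort == "control"])))
  cat(sprintf("  coverage profiles: %s\n",
              if (is.null(object@coverageCase) &&
                  is.null(object@coverageControl)) "none" else "present"))
})

#' @describeIn filterRare filter the rows of a variant data.frame.
#' @export
setMethod("filterRare", "data.frame", function(x, afThreshold = 1e-4) {
  stopifnot(is.numeric(afThreshold), length(afThreshold) == 1L,
            afThreshold > 0, afThreshold < 1)
  if (!nrow(x)) return(x)
  keep <- is.na(x$popmax_af) | x$popmax_af < afThreshold
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @describeIn filterRare filter the variants of a GeneDataset in place.
#' @export
setMethod("filterRare", "GeneDataset", function(x, afThreshold = 1e-4) {
  x@variants <- filterRare(x@variants, afThreshold)
  validObject(x)
  x
})

#' Carrier and non-carrier totals per cohort
#'
#' Sums carrier counts over the variant records of each cohort and derives
#' the complementary non-carrier counts from the cohort sizes. Carriers and
#' non-carriers always add up to the cohort size.
#'
#' @param x a \linkS4class{GeneDataset}.
#' @return named integer vector with elements \code{case_carriers},
#'   \code{control_carriers}, \code{case_noncarriers},
#'   \code{control_noncarriers}.
#' @examples
#' v <- data.frame(position = c(5L, 9L, 9L), cohort = "case",
#'                 carrier_count = c(1L, 2L, 1L), popmax_af = NA_real_)
#' ds <- GeneDataset("MYL2", 166L, 100L, 200L, v)
#' carrierSummary(ds)
#' @export
setMethod("carrierSummary", "GeneDataset", function(x) {
  v <- x@variants
  cc <- sum(v$carrier_count[v$cohort == "case"])
  kc <- sum(v$carrier_count[v$cohort == "control"])
  out <- c(case_carriers = cc, control_carriers = kc,
           case_noncarriers = x@nCases - cc,
           control_noncarriers = x@nControls - kc)
  if (any(out < 0))
    stop("carrier counts exceed cohort size; non-carrier count would be ",
         "negative")
  as.integer(out) -> res
  names(res) <- names(out)
  res
})

# Residue positions of one cohort, expanded to one entry per carrier
# (carrier_count copies) unless distinct = TRUE. Order follows the variant
# table, which keeps score alignment trivial for the GAM frame.
cohortPositions <- function(ds, cohort, distinct = FALSE) {
  v <- ds@variants[ds@variants$cohort == cohort, , drop = FALSE]
  if (!nrow(v)) return(integer(0))
  if (distinct) v$position else rep(v$position, v$carrier_count)
}

#' Attach coverage profiles to a GeneDataset
#'
#' @param ds a \linkS4class{GeneDataset}.
#' @param coverage nested list as returned by \code{\link{readCoverage}},
#'   or a list with elements \code{case} and/or \code{control}.
#' @return the dataset with coverage slots filled.
#' @export
attachCoverage <- function(ds, coverage) {
  if (!is.null(coverage[[ds@gene]])) coverage <- coverage[[ds@gene]]
  if (!is.null(coverage$case)) ds@coverageCase <- as.numeric(coverage$case)
  if (!is.null(coverage$control))
    ds@coverageControl <- as.numeric(coverage$control)
  validObject(ds)
  ds
}
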