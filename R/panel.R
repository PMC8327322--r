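#' Scan a gene panel with burden, BIN-test and ClusterBurden
#'
#' Runs the three association tests on every gene of a panel and marks
#' each p-value as \code{"significant"} against the Bonferroni threshold
#' alpha_family / (3 x number of genes), \code{"nominal"} against 0.05, or
#' \code{"ns"}. Genes without any variant record are reported with all
#' tests undefined (NA).
#'
#' @param datasets list of \linkS4class{GeneDataset} objects.
#' @param alphaFamily family-wise error rate (default 0.05).
#' @param useCoverage passed to the component tests.
#' @return a \linkS4class{PanelScan}.
#' @examples
#' v <- data.frame(position = c(10L, 150L), cohort = c("case", "control"),
#'                 carrier_count = c(3L, 2L), popmax_af = NA_real_)
#' ds <- GeneDataset("TNNT2", 298L, 500L, 5000L, v)
#' scanPanel(list(ds))
#' @export
scanPanel <- function(datasets, alphaFamily = 0.05, useCoverage = FALSE) {
  stopifnot(length(datasets) >= 1, alphaFamily > 0, alphaFamily < 1)
  nTests <- 3L * length(datasets)
  alphaPer <- alphaFamily / nTests
  flag <- function(p) {
    ifelse(is.na(p), NA_character_,
           ifelse(p < alphaPer, "significant",
                  ifelse(p < 0.05, "nominal", "ns")))
  }
  rows <- lapply(datasets, function(ds) {
    if (!nrow(ds@variants)) {
      return(data.frame(gene = ds@gene, n_case_variants = 0L,
                        n_control_variants = 0L, p_burden = NA_real_,
                        p_cluster = NA_real_, p_combined = NA_real_,
                        stat_cluster = NA_real_, df_cluster = NA_integer_,
                        degenerate = NA, stringsAsFactors = FALSE))
    }
    as.data.frame(clusterBurden(ds, useCoverage = useCoverage))
  })
  res <- do.call(rbind, rows)
  res$burden_call <- flag(res$p_burden)
  res$cluster_call <- flag(res$p_cluster)
  res$combined_call <- flag(res$p_combined)
  rownames(res) <- NULL
  new("PanelScan", results = res, alphaFamily = alphaFamily,
      nTests = nTests, alphaPerTest = alphaPer)
}

#' @describeIn PanelScan-class per-gene result data.frame.
#' @export
setMethod("panelResults", "PanelScan", function(x) x@results)

#' @describeIn PanelScan-class Bonferroni per-test threshold.
#' @export
setMethod("alphaPerTest", "PanelScan", function(x) x@alphaPerTest)

setMethod("show", "PanelScan", function(object) {
  cat(sprintf(
    "PanelScan: %d genes, %d tests, alpha %.3g -> per-test %.3g\n",
    nrow(object@results), object@nTests, object@alphaFamily,
    object@alphaPerTest))
  print(utils::head(object@results, 10))
  if (nrow(object@results) > 10) cat("  ...\n")
})
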