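#' Number of bins for the BIN-test
#'
#' Applies the k ~ n^(2/5) heuristic to the total (case + control) number
#' of observed variants, rounding half up and flooring at 2 bins.
#'
#' @param nTotalVariants combined number of observed variants.
#' @return integer bin count k.
#' @examples
#' chooseBinCount(32)   # 32^(2/5) = 4
#' chooseBinCount(100)  # 100^(2/5) = 6.31 -> 6
#' @export
chooseBinCount <- function(nTotalVariants) {
  stopifnot(nTotalVariants >= 0)
  max(2L, as.integer(floor(nTotalVariants^0.4 + 0.5)))
}

# Bin index of residue r among k equal-length bins over [1, L]:
# min(k, ceiling(r * k / L)). Bins are half-open [lo, hi) except the last.
binIndex <- function(positions, L, k) {
  pmin.int(k, as.integer(ceiling(positions * k / L)))
}

#' Bin residue positions into k equal-length bins
#'
#' @param positions integer residue positions in [1, L].
#' @param L protein length.
#' @param k number of bins (>= 2).
#' @return length-k integer count vector; counts sum to
#'   \code{length(positions)}.
#' @examples
#' binPositions(c(1, 25, 26, 100), L = 100, k = 4)  # 2 1 0 1
#' @export
binPositions <- function(positions, L, k) {
  stopifnot(k >= 2L, L >= 1L)
  if (length(positions) && (any(positions < 1) || any(positions > L)))
    stop("positions must lie in [1, L]")
  if (!length(positions)) return(integer(k))
  tabulate(binIndex(positions, L, k), nbins = k)
}

#' Bin boundaries for k equal-length bins over [1, L]
#'
#' @inheritParams binPositions
#' @return numeric vector of k+1 strictly increasing edges.
#' @export
binEdges <- function(L, k) {
  c(1, (seq_len(k) * L) / k)
}

#' Coverage-adjust binned counts
#'
#' Divides each bin's count by the mean 10x coverage over the residues of
#' that bin, so that counts from poorly covered regions are scaled up by
#' the reciprocal of their coverage. Adjusted counts may be non-integer.
#'
#' @param counts length-k count vector.
#' @param coverage per-residue coverage vector (length L), values in
#'   (0, 1].
#' @param L protein length.
#' @param k number of bins.
#' @return length-k real vector of adjusted counts.
#' @export
adjustBinCounts <- function(counts, coverage, L, k = length(counts)) {
  stopifnot(length(counts) == k, length(coverage) == L)
  idx <- binIndex(seq_len(L), L, k)
  meanCov <- vapply(seq_len(k),
                    function(j) mean(coverage[idx == j]), numeric(1))
  if (any(!is.finite(meanCov) | meanCov <= 0))
    stop("mean bin coverage must be positive for every bin")
  counts / meanCov
}

#' Build the k x 2 binned positional count table for a gene
#'
#' @param ds a \linkS4class{GeneDataset}.
#' @param useCoverage adjust each cohort's bin counts by the reciprocal of
#'   its mean bin coverage (only when that cohort's profile is present).
#' @param distinct count each variant record once instead of once per
#'   carrier.
#' @param k bin count; defaults to \code{\link{chooseBinCount}} on the
#'   combined number of observations.
#' @return a \linkS4class{BinTable}.
#' @export
binTable <- function(ds, useCoverage = FALSE, distinct = FALSE, k = NULL) {
  L <- ds@proteinLength
  posCase <- cohortPositions(ds, "case", distinct)
  posCtrl <- cohortPositions(ds, "control", distinct)
  if (is.null(k)) k <- chooseBinCount(length(posCase) + length(posCtrl))
  cc <- binPositions(posCase, L, k)
  ck <- binPositions(posCtrl, L, k)
  adjusted <- FALSE
  if (useCoverage) {
    if (!is.null(ds@coverageCase)) {
      cc <- adjustBinCounts(cc, ds@coverageCase, L, k)
      adjusted <- TRUE
    }
    if (!is.null(ds@coverageControl)) {
      ck <- adjustBinCounts(ck, ds@coverageControl, L, k)
      adjusted <- TRUE
    }
  }
  new("BinTable", k = as.integer(k), edges = binEdges(L, k),
      countsCase = as.numeric(cc), countsControl = as.numeric(ck),
      adjusted = adjusted)
}

setMethod("show", "BinTable", function(object) {
  cat(sprintf("BinTable: %d bins%s\n", object@k,
              if (object@adjusted) " (coverage-adjusted)" else ""))
  m <- rbind(case = object@countsCase, control = object@countsControl)
  colnames(m) <- sprintf("b%d", seq_len(object@k))
  print(round(m, 2))
})

# Pearson chi-squared statistic on a 2 x k' table with expectations from
# the margins; bins with zero combined count are dropped by the caller.
chisqStat <- function(countsCase, countsControl) {
  O <- rbind(countsCase, countsControl)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

#' BIN-test: binned chi-squared test of differential positional clustering
#'
#' Compares the positional distributions of rare missense variants between
#' cases and controls. The protein is split into k equal-length bins (k
#' from the n^(2/5) heuristic on the combined observation count), the
#' variants of each cohort are counted per bin (optionally
#' coverage-adjusted), and a chi-squared two-sample test is applied to the
#' resulting k x 2 contingency table. Bins with zero combined count are
#' dropped with a matching reduction in degrees of freedom; no continuity
#' correction is applied.
#'
#' @inheritParams binTable
#' @return list with elements \code{statistic}, \code{df}, \code{p.value},
#'   \code{k} (heuristic bin count), \code{kRetained} (bins with nonzero
#'   combined counts), \code{table} (the \linkS4class{BinTable}) and
#'   \code{degenerate} (TRUE, with p = 1 and df = 0, when fewer than two
#'   bins are retained).
#' @examples
#' v <- data.frame(
#'   position = c(10L, 40L, 60L, 90L),
#'   cohort = c("case", "case", "control", "control"),
#'   carrier_count = c(10L, 10L, 10L, 10L), popmax_af = NA_real_)
#' ds <- GeneDataset("TTN", 100L, 1000L, 1000L, v)
#' binTest(ds)  # statistic 40 on 3 df
#' @export
binTest <- function(ds, useCoverage = FALSE, distinct = FALSE) {
  bt <- binTable(ds, useCoverage = useCoverage, distinct = distinct)
  cc <- bt@countsCase
  ck <- bt@countsControl
  keep <- (cc + ck) > 0
  degenerate <- sum(keep) < 2L || sum(cc) == 0 || sum(ck) == 0
  if (degenerate) {
    warning("BIN-test degenerate: fewer than two informative bins")
    return(list(statistic = 0, df = 0L, p.value = 1, k = bt@k,
                kRetained = sum(keep), table = bt, degenerate = TRUE))
  }
  stat <- chisqStat(cc[keep], ck[keep])
  df <- sum(keep) - 1L
  list(statistic = stat, df = as.integer(df),
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       k = bt@k, kRetained = as.integer(sum(keep)), table = bt,
       degenerate = FALSE)
}
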