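# Mean coverage in a +/- window residues neighbourhood of pos, clipped to
# [1, L]. Returns 1 when no profile is available.
windowMeanCoverage <- function(coverage, pos, window, L) {
  if (is.null(coverage)) return(rep(1, length(pos)))
  lo <- pmax(1L, pos - window)
  hi <- pmin(L, pos + window)
  vapply(seq_along(pos),
         function(i) mean(coverage[lo[i]:hi[i]]), numeric(1))
}

#' Assemble the model frame for a hotspot GAM
#'
#' Builds the weighted binomial model frame: one row per carrier (carrier
#' counts expanded), with the case/control indicator as response, the
#' residue position, and a weight equal to the reciprocal of the mean 10x
#' coverage in the surrounding +/- \code{coverageWindow} residues of that
#' carrier's cohort; plus two aggregated non-carrier rows (one per cohort)
#' whose frequency weights are the non-carrier count times the reciprocal
#' gene-wide mean coverage. Without coverage profiles all coverage factors
#' are 1. Datasets with fewer than \code{minCarriers} carriers in total
#' are refused (the positional smooth is not identifiable from a handful
#' of observations) unless \code{force = TRUE}.
#'
#' @param ds a \linkS4class{GeneDataset}.
#' @param coverageWindow half-width, in residues, of the coverage window
#'   for carrier weights (default 15).
#' @param minCarriers minimum total carrier observations (default 20).
#' @param force fit anyway below the carrier threshold.
#' @return a \linkS4class{GamFrame}.
#' @export
assembleGamFrame <- function(ds, coverageWindow = 15L, minCarriers = 20L,
                             force = FALSE) {
  v <- ds@variants
  L <- ds@proteinLength
  nCarriers <- sum(v$carrier_count)
  if (nCarriers < minCarriers && !force)
    stop(sprintf(paste0("only %d carrier observations (< %d): too few to ",
                        "estimate a positional smooth; use force = TRUE ",
                        "to override"), nCarriers, minCarriers))
  cs <- carrierSummary(ds)
  rows <- lapply(c("case", "control"), function(ch) {
    vv <- v[v$cohort == ch, , drop = FALSE]
    if (!nrow(vv)) return(NULL)
    cov <- coverageProfile(ds, ch)
    w <- 1 / windowMeanCoverage(cov, vv$position, coverageWindow, L)
    idx <- rep(seq_len(nrow(vv)), vv$carrier_count)
    data.frame(is_case = as.integer(ch == "case"),
               carrier = 1,
               position = vv$position[idx],
               weight = w[idx],
               variant_row = which(v$cohort == ch)[idx])
  })
  geneMean <- function(ch) {
    cov <- coverageProfile(ds, ch)
    if (is.null(cov)) 1 else mean(cov)
  }
  agg <- data.frame(
    is_case = c(1L, 0L), carrier = 0, position = 0,
    weight = c(cs[["case_noncarriers"]] / geneMean("case"),
               cs[["control_noncarriers"]] / geneMean("control")),
    variant_row = NA_integer_)
  fr <- rbind(do.call(rbind, rows), agg)
  fr$carrierO <- stats::relevel(factor(fr$carrier, levels = c(0, 1)), "0")
  fr$carrierO <- as.ordered(fr$carrierO)
  rownames(fr) <- NULL
  new("GamFrame", frame = fr, gene = ds@gene, L = L,
      coverageWindow = as.integer(coverageWindow))
}

setMethod("show", "GamFrame", function(object) {
  fr <- object@frame
  cat(sprintf(
    "GamFrame: %s (L = %d), %d carrier rows + 2 aggregate rows\n",
    object@gene, object@L, sum(fr$carrier == 1)))
  cat(sprintf("  total weight: cases %.1f, controls %.1f\n",
              sum(fr$weight[fr$is_case == 1]),
              sum(fr$weight[fr$is_case == 0])))
})

gamFormula <- function(basisDim, features = character(0)) {
  rhs <- sprintf("carrier + s(position, by = carrierO, bs = \"ps\", k = %d, m = c(2, 2))",
                 basisDim)
  if (length(features))
    rhs <- paste(c(rhs, features), collapse = " + ")
  stats::as.formula(paste("is_case ~", rhs))
}

# Shared fitting path for hotspot and hotspot+ models. `data` must carry
# any (already centred, carrier-nested) feature columns named in
# `features`.
fitHotspotEngine <- function(frame, data, basisDim, smoothing, features,
                             featureMeans, sp = NULL) {
  carriers <- data[data$carrier == 1, , drop = FALSE]
  if (length(unique(carriers$is_case)) < 2L)
    stop("quasi-complete separation: all carriers belong to one cohort; ",
         "the carrier log-odds ratio is not estimable")
  method <- switch(smoothing, REML = "REML", GCV = "GCV.Cp")
  fit <- mgcv::gam(gamFormula(basisDim, features),
                   family = stats::binomial(), weights = weight,
                   data = data, method = method, sp = sp)
  if (!fit$converged)
    stop("GAM fit did not converge; last deviance: ", fit$deviance)
  new("HotspotModel", fit = fit, gene = frame@gene, L = frame@L,
      basisDim = as.integer(basisDim), smoothing = smoothing,
      features = features, featureMeans = featureMeans)
}

#' Fit the hotspot model
#'
#' Fits the nested binomial GAM \code{P(case) = b0 + b1 carrier +
#' s(position, by = carrier)} by penalized likelihood: the residue-position
#' effect enters only through its interaction with carrier status (the
#' smooth is multiplied by zero for non-carriers, whose position is
#' undefined), is represented by a cubic P-spline basis with a
#' second-order difference penalty and a sum-to-zero centering constraint,
#' and has its smoothing parameter chosen by REML (or GCV). The
#' coefficient covariance is the Bayesian posterior covariance of the
#' penalized fit.
#'
#' @param frame a \linkS4class{GamFrame}.
#' @param basisDim spline basis dimension (default 10).
#' @param smoothing smoothing-parameter selection criterion: "REML"
#'   (default) or "GCV".
#' @param sp optional fixed smoothing parameter, bypassing selection
#'   (0 gives the unpenalized fit, very large values force the smooth to
#'   its penalty null space, i.e. a straight line).
#' @return a \linkS4class{HotspotModel}.
#' @seealso \code{\link{predictPositionOR}}, \code{\link{fitHotspotPlus}}
#' @export
fitHotspot <- function(frame, basisDim = 10L,
                       smoothing = c("REML", "GCV"), sp = NULL) {
  smoothing <- match.arg(smoothing)
  stopifnot(is(frame, "GamFrame"))
  fitHotspotEngine(frame, frame@frame, basisDim, smoothing,
                   character(0), numeric(0), sp = sp)
}

#' @describeIn HotspotModel-class effective degrees of freedom of the
#'   position smooth.
#' @export
setMethod("modelEDF", "HotspotModel",
          function(x) sum(x@fit$edf[x@fit$smooth[[1]]$first.para:
                                    x@fit$smooth[[1]]$last.para]))

#' @describeIn HotspotModel-class selected smoothing parameter(s).
#' @export
setMethod("smoothingParameter", "HotspotModel", function(x) x@fit$sp)

#' @describeIn HotspotModel-class in-silico features included in the
#'   model (empty for plain hotspot models).
#' @export
setMethod("selectedFeatures", "HotspotModel", function(x) x@features)

setMethod("show", "HotspotModel", function(object) {
  cat(sprintf("HotspotModel: %s (L = %d), basis dim %d, %s smoothing\n",
              object@gene, object@L, object@basisDim, object@smoothing))
  cat(sprintf("  smooth edf %.2f, lambda %.3g\n", modelEDF(object),
              object@fit$sp[1]))
  if (length(object@features))
    cat("  features:", paste(object@features, collapse = ", "), "\n")
})

# Linear-predictor design rows for carrier observations at given positions
# and (optional) centred feature values, minus the non-carrier baseline
# row. Returns the contrast matrix D such that log OR = D %*% coef.
orContrast <- function(model, positions, featureValues = NULL) {
  nd <- data.frame(carrier = c(0, rep(1, length(positions))),
                   position = c(0, positions))
  nd$carrierO <- as.ordered(factor(nd$carrier, levels = c(0, 1)))
  for (f in model@features) {
    val <- if (is.null(featureValues)) rep(0, length(positions)) else
      featureValues[[f]]
    nd[[f]] <- c(0, val)
  }
  Xp <- mgcv::predict.gam(model@fit, newdata = nd, type = "lpmatrix")
  sweep(Xp[-1, , drop = FALSE], 2, Xp[1, ], "-")
}

orFromContrast <- function(model, D, positions) {
  beta <- stats::coef(model@fit)
  V <- stats::vcov(model@fit)
  logOR <- drop(D %*% beta)
  se <- sqrt(rowSums((D %*% V) * D))
  data.frame(position = positions, log_or = logOR, se = se,
             or = exp(logOR),
             ci_low = exp(logOR - 1.96 * se),
             ci_high = exp(logOR + 1.96 * se),
             evidence = stratifyEvidence(exp(logOR)))
}

#' Per-position odds ratios from a hotspot model
#'
#' The log odds ratio at residue x is b1 + s(x): the log odds of case
#' status for a carrier of a variant at x versus a non-carrier. Standard
#' errors come from the delta-method quadratic form over the coefficient
#' covariance; 95\% confidence bounds are exp(log OR -/+ 1.96 se). For
#' hotspot+ models the in-silico features are held at their training
#' means, so the curve is the positional profile at an average score.
#'
#' @param model a \linkS4class{HotspotModel}.
#' @param positions integer residue positions in [1, L] (default: every
#'   residue).
#' @return data.frame with columns position, log_or, se, or, ci_low,
#'   ci_high and evidence (see \code{\link{stratifyEvidence}}).
#' @export
predictPositionOR <- function(model, positions = seq_len(model@L)) {
  stopifnot(is(model, "HotspotModel"))
  if (any(positions < 1 | positions > model@L))
    stop("positions must lie in [1, L]")
  D <- orContrast(model, positions)
  orFromContrast(model, D, positions)
}

#' Per-variant odds ratios from a hotspot+ model
#'
#' As \code{\link{predictPositionOR}}, but the log odds ratio of each
#' variant additionally includes its in-silico feature terms: b1 + s(x) +
#' sum_j g_j score_j. Missing scores are imputed at the training mean.
#'
#' @param model a \linkS4class{HotspotModel}.
#' @param variants data.frame with a \code{position} column and one
#'   column per selected feature.
#' @return data.frame as in \code{\link{predictPositionOR}}.
#' @export
predictVariantOR <- function(model, variants) {
  stopifnot(is(model, "HotspotModel"), "position" %in% names(variants))
  positions <- variants$position
  if (any(positions < 1 | positions > model@L))
    stop("positions must lie in [1, L]")
  fv <- lapply(model@features, function(f) {
    x <- if (f %in% names(variants)) variants[[f]] else
      rep(NA_real_, nrow(variants))
    x <- x - model@featureMeans[[f]]   # centring; mean-imputes NA as 0
    x[is.na(x)] <- 0
    x
  })
  names(fv) <- model@features
  D <- orContrast(model, positions, fv)
  orFromContrast(model, D, positions)
}

#' Evidence stratum for an odds ratio
#'
#' Maps a predicted odds ratio to an ACMG-style evidence stratum for the
#' combined mutational-hotspot / computational criteria: OR >= 100 strong,
#' >= 20 moderate, >= 10 supporting, >= 5 weak, otherwise none.
#'
#' @param orValue positive odds ratio(s).
#' @return ordered factor with levels none < weak < supporting <
#'   moderate < strong.
#' @examples
#' stratifyEvidence(c(1, 9.999, 15, 150))
#' @export
stratifyEvidence <- function(orValue) {
  stopifnot(all(orValue > 0))
  lev <- c("none", "weak", "supporting", "moderate", "strong")
  idx <- 1L + (orValue >= 5) + (orValue >= 10) + (orValue >= 20) +
    (orValue >= 100)
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Convert a case probability to odds
#'
#' Odds = p / (1 - p). Probability thresholds 0.9, 0.95 and 0.99
#' correspond to odds of 9, 19 and 99 (approximately 10, 20 and 100).
#'
#' @param p probability strictly inside (0, 1).
#' @return the odds.
#' @export
probabilityOddsMap <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  p / (1 - p)
}

#' Empirical odds ratio with Haldane continuity correction
#'
#' Computes the empirical 2 x 2 odds ratio (a d) / (b c) for carriers and
#' non-carriers, adding 0.5 to all four cells when any cell is zero
#' (Haldane correction), with a 95\% Woolf confidence interval
#' exp(log OR -/+ 1.96 sqrt(sum of reciprocal cells)).
#'
#' @param caseCarriers,caseNon,controlCarriers,controlNon the four cells.
#' @return named numeric vector \code{c(or, ci_low, ci_high)}.
#' @examples
#' empiricalORHaldane(1, 9, 0, 100)  # corrected cells: OR = 31.74
#' @export
empiricalORHaldane <- function(caseCarriers, caseNon, controlCarriers,
                               controlNon) {
  cells <- c(caseCarriers, caseNon, controlCarriers, controlNon)
  stopifnot(all(cells >= 0))
  if (caseCarriers == 0 && controlCarriers == 0)
    stop("no carriers in either cohort: the odds ratio is undefined")
  if (any(cells == 0)) cells <- cells + 0.5
  orv <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  seLog <- sqrt(sum(1 / cells))
  c(or = orv, ci_low = exp(log(orv) - 1.96 * seLog),
    ci_high = exp(log(orv) + 1.96 * seLog))
}
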