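# Expanded carrier-level view of a SimulatedDataset's truth, in the same
# order as the carrier rows of assembleGamFrame on its dataset.
expandTruth <- function(simds) {
  v <- simds@dataset@variants
  tr <- simds@truth
  out <- lapply(c("case", "control"), function(ch) {
    idx <- which(v$cohort == ch)
    if (!length(idx)) return(NULL)
    rep(idx, v$carrier_count[idx])
  })
  idx <- unlist(out)
  data.frame(variant_row = idx, position = v$position[idx],
             cohort = v$cohort[idx], pathogenic = tr$pathogenic[idx],
             true_log_or = log(tr$true_or[idx]))
}

#' Generate synthetic in-silico predictor scores
#'
#' Stands in for a dbNSFP-style score extraction: produces one row per
#' carrier observation (aligned with the carrier rows of
#' \code{\link{assembleGamFrame}} on the simulated dataset) and
#' \code{nFeatures} columns. Informative features are the standardized
#' true per-variant log odds ratio scaled by the requested effect size
#' plus standard-normal noise; all other features are pure standard-normal
#' noise. An effect size of 0 therefore yields a column independent of the
#' truth.
#'
#' @param simds a \linkS4class{SimulatedDataset}.
#' @param nFeatures number of candidate features (default 24).
#' @param informative named numeric vector: effect sizes keyed by feature
#'   index (e.g. \code{c("1" = 2)} makes feature_01 informative with
#'   effect 2), or a 2-column matrix of (index, effect).
#' @param seed optional integer seed; identical seeds give identical
#'   matrices.
#' @return numeric matrix with columns \code{feature_01} ... and
#'   attributes \code{variant_row}, \code{position}, \code{cohort},
#'   \code{true_log_or} describing the carrier rows.
#' @export
generateSyntheticScores <- function(simds, nFeatures = 24L,
                                    informative = NULL, seed = NULL) {
  stopifnot(nFeatures >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tr <- expandTruth(simds)
  n <- nrow(tr)
  X <- matrix(stats::rnorm(n * nFeatures), nrow = n,
              dimnames = list(NULL, sprintf("feature_%02d",
                                            seq_len(nFeatures))))
  if (!is.null(informative)) {
    if (is.matrix(informative))
      informative <- stats::setNames(informative[, 2],
                                     as.character(informative[, 1]))
    sig <- tr$true_log_or
    sig <- if (stats::sd(sig) > 0) (sig - mean(sig)) / stats::sd(sig)
           else rep(0, n)
    for (j in names(informative)) {
      jj <- as.integer(j)
      stopifnot(jj >= 1L, jj <= nFeatures)
      X[, jj] <- X[, jj] + informative[[j]] * sig
    }
  }
  attr(X, "variant_row") <- tr$variant_row
  attr(X, "position") <- tr$position
  attr(X, "cohort") <- tr$cohort
  attr(X, "true_log_or") <- tr$true_log_or
  X
}

# Attach centred, carrier-nested feature columns to a GamFrame's frame.
# X has one row per carrier row; non-carrier rows get zeros (the features
# are nested within carrier status, mirroring the position smooth).
frameWithFeatures <- function(frame, X, features) {
  fr <- frame@frame
  nCarrier <- sum(fr$carrier == 1)
  if (nrow(X) != nCarrier)
    stop(sprintf("feature matrix has %d rows but the frame has %d carrier rows",
                 nrow(X), nCarrier))
  means <- numeric(0)
  for (f in features) {
    x <- X[, f]
    mu <- mean(x, na.rm = TRUE)
    x <- x - mu
    x[is.na(x)] <- 0   # mean imputation within gene
    col <- numeric(nrow(fr))
    col[fr$carrier == 1] <- x
    fr[[f]] <- col
    means[f] <- mu
  }
  list(frame = fr, means = means)
}

waldP <- function(fit, terms) {
  beta <- stats::coef(fit)[terms]
  se <- sqrt(diag(stats::vcov(fit))[terms])
  stats::setNames(2 * stats::pnorm(-abs(beta / se)), terms)
}

#' Two-stage in-silico feature selection
#'
#' Stage 1 adds each candidate feature alone, as a linear carrier-nested
#' term, to the hotspot model and keeps those whose Wald p-value passes
#' the Bonferroni bound 0.05 / (number of candidates). Stage 2 fits the
#' joint model with all stage-1 survivors and repeatedly removes the
#' feature with the largest p-value until every remaining feature passes
#' 0.05 / (number of stage-1 survivors). An empty final set is a valid
#' outcome.
#'
#' @param frame a \linkS4class{GamFrame}.
#' @param X feature matrix from \code{\link{generateSyntheticScores}} (or
#'   a dbNSFP-like score matrix aligned to the carrier rows).
#' @param candidates candidate feature columns (default: all columns).
#' @param basisDim,smoothing passed to the underlying GAM fits.
#' @param alphaFamily family-wise level split over candidates (default
#'   0.05).
#' @return list with \code{stage1_pvalues}, \code{stage1_selected},
#'   \code{elimination_path} (data.frame of feature and p at removal),
#'   \code{final_features}, \code{stage1_alpha}, \code{stage2_alpha}.
#' @export
selectFeatures <- function(frame, X, candidates = colnames(X),
                           basisDim = 10L, smoothing = "REML",
                           alphaFamily = 0.05) {
  stopifnot(all(candidates %in% colnames(X)))
  stage1Alpha <- alphaFamily / length(candidates)
  p1 <- vapply(candidates, function(f) {
    wf <- frameWithFeatures(frame, X, f)
    fit <- fitHotspotEngine(frame, wf$frame, basisDim, smoothing, f,
                            wf$means)
    waldP(fit@fit, f)[[f]]
  }, numeric(1))
  selected <- candidates[p1 < stage1Alpha]
  stage2Alpha <- if (length(selected)) alphaFamily / length(selected)
                 else NA_real_
  path <- data.frame(feature = character(0), p_at_removal = numeric(0))
  final <- selected
  while (length(final)) {
    wf <- frameWithFeatures(frame, X, final)
    fit <- fitHotspotEngine(frame, wf$frame, basisDim, smoothing, final,
                            wf$means)
    pj <- waldP(fit@fit, final)
    if (max(pj) < stage2Alpha) break
    worst <- names(which.max(pj))
    path <- rbind(path, data.frame(feature = worst,
                                   p_at_removal = max(pj)))
    final <- setdiff(final, worst)
  }
  list(stage1_pvalues = p1, stage1_selected = selected,
       elimination_path = path, final_features = final,
       stage1_alpha = stage1Alpha, stage2_alpha = stage2Alpha)
}

#' Fit a hotspot+ model
#'
#' The hotspot model plus unpenalized linear terms for the selected
#' in-silico features, nested within carrier status (zero for
#' non-carriers) and centred at their training means. The per-variant log
#' odds ratio becomes b1 + s(position) + sum_j g_j score_j, so variants at
#' the same residue with different scores receive different odds ratios.
#' With an empty feature set the fit is exactly the hotspot model.
#'
#' @inheritParams selectFeatures
#' @param features feature columns to include (typically
#'   \code{final_features} from \code{\link{selectFeatures}}).
#' @return a \linkS4class{HotspotModel} with feature coefficients.
#' @export
fitHotspotPlus <- function(frame, X, features = character(0),
                           basisDim = 10L, smoothing = c("REML", "GCV")) {
  smoothing <- match.arg(smoothing)
  if (!length(features))
    return(fitHotspot(frame, basisDim = basisDim, smoothing = smoothing))
  wf <- frameWithFeatures(frame, X, features)
  Xf <- as.matrix(wf$frame[wf$frame$carrier == 1, features, drop = FALSE])
  if (qr(Xf)$rank < length(features)) {
    stop("collinear feature set: ", paste(features, collapse = ", "),
         " are rank deficient among carriers")
  }
  fitHotspotEngine(frame, wf$frame, basisDim, smoothing, features,
                   wf$means)
}

# Wilcoxon/Mann-Whitney AUC of scores for a 0/1 outcome.
rankAUC <- function(score, outcome) {
  r <- rank(score)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Held-out AUC over repeated stratified 80/20 splits
#'
#' Evaluates a model specification by 10 (by default) independent random
#' splits of the carrier observations, stratified by case/control status,
#' at an 80\%:20\% train:test ratio. The model is refitted on each
#' training split (the two aggregated non-carrier rows are always kept in
#' the training data) and the AUC of the predicted case probability is
#' computed on the held-out carriers.
#'
#' @inheritParams fitHotspotPlus
#' @param useSmooth include the positional smooth (FALSE gives a
#'   burden-plus-features logistic model, e.g. for single-predictor
#'   comparisons).
#' @param nSplits number of random splits (default 10).
#' @param ratio training fraction (default 0.8).
#' @param seed optional integer seed.
#' @return list with \code{mean_auc}, \code{sd_auc}, \code{per_split_auc},
#'   \code{n_splits}, \code{ratio}.
#' @export
crossfoldAUC <- function(frame, X = NULL, features = character(0),
                         useSmooth = TRUE, basisDim = 10L,
                         smoothing = "REML", nSplits = 10L, ratio = 0.8,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(features)) {
    wf <- frameWithFeatures(frame, X, features)
    fr <- wf$frame
  } else {
    fr <- frame@frame
  }
  carrierIdx <- which(fr$carrier == 1)
  aggIdx <- which(fr$carrier == 0)
  cls <- fr$is_case[carrierIdx]
  if (sum(cls == 1) < 10L || sum(cls == 0) < 10L)
    stop("need at least 10 carriers per cohort for held-out evaluation")
  fitOne <- function(trainRows) {
    dat <- fr[c(trainRows, aggIdx), , drop = FALSE]
    if (useSmooth) {
      method <- switch(smoothing, REML = "REML", GCV = "GCV.Cp")
      mgcv::gam(gamFormula(basisDim, features),
                family = stats::binomial(), weights = weight, data = dat,
                method = method)
    } else {
      rhs <- paste(c("carrier", features), collapse = " + ")
      stats::glm(stats::as.formula(paste("is_case ~", rhs)),
                 family = stats::binomial(), weights = weight, data = dat)
    }
  }
  aucs <- vapply(seq_len(nSplits), function(s) {
    for (try in 1:10) {
      trainRows <- unlist(lapply(c(0, 1), function(y) {
        rows <- carrierIdx[cls == y]
        sample(rows, size = floor(ratio * length(rows)))
      }))
      testRows <- setdiff(carrierIdx, trainRows)
      if (length(unique(fr$is_case[testRows])) == 2L) break
      if (try == 10) stop("could not draw a two-class test split")
    }
    fit <- fitOne(trainRows)
    pred <- stats::predict(fit, newdata = fr[testRows, , drop = FALSE],
                           type = "response")
    rankAUC(pred, fr$is_case[testRows])
  }, numeric(1))
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
       per_split_auc = aucs, n_splits = as.integer(nSplits),
       ratio = ratio)
}
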