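# Evaluation suite: concordance, IPCW time-dependent AUC / IAUC, logrank,
# Nagelkerke pseudo R^2, IPCW Brier score, Signature Skill Score,
# calibration, variance inflation.

#' Harrell's concordance index
#'
#' Computes the pair-counting concordance
#' `c = 1/2 * ((C - D) / (C + D + Tx) + 1)`, where C, D and Tx count
#' concordant, discordant and prediction-tied comparable pairs. A pair is
#' comparable iff the member with the shorter follow-up had an event;
#' outcome-time ties are incomparable; prediction ties count 1/2.
#'
#' @param scores per-patient scores, higher = longer predicted survival
#'   (pass the negated linear predictor of a risk model)
#' @param outcome data.frame(time, status)
#' @return concordance in [0, 1]
#' @export
concordanceIndex <- function(scores, outcome) {
  checkOutcome(outcome)
  t <- outcome$time
  d <- outcome$status
  s <- as.numeric(scores)
  stopifnot(length(s) == length(t))
  shorter <- outer(t, t, "<") & (d == 1)   # [i,j]: t_i < t_j, i had event
  C <- sum(shorter & outer(s, s, "<"))
  D <- sum(shorter & outer(s, s, ">"))
  Tx <- sum(shorter & outer(s, s, "=="))
  if (C + D + Tx == 0) stop("no comparable pairs")
  0.5 * ((C - D) / (C + D + Tx) + 1)
}

#' IPCW time-dependent AUC curve and IAUC
#'
#' Cumulative-case / dynamic-control AUC(t): at each grid time, cases are
#' patients with an observed event by t (weighted by the inverse
#' Kaplan-Meier censoring survival at their event time), controls are
#' patients still event-free past t (weighted at t). AUC(t) estimates the
#' probability that a randomly chosen case/control pair is correctly
#' ranked at t; without censoring it reduces to the Mann-Whitney
#' statistic. The IAUC is the trapezoidal mean of AUC(t) over the grid.
#'
#' @param scores per-patient scores, higher = longer predicted survival
#' @param outcome data.frame(time, status)
#' @param grid evaluation times (default: unique event times up to
#'   `horizon`); times with no cases or no controls are dropped with a
#'   warning
#' @param horizon truncation for the default grid (years)
#' @return list with `curve` (data.frame time, auc) and `iauc`
#' @export
tdAucCurve <- function(scores, outcome, grid = NULL, horizon = 10) {
  checkOutcome(outcome)
  t <- outcome$time
  d <- outcome$status
  s <- as.numeric(scores)
  if (is.null(grid))
    grid <- sort(unique(t[d == 1 & t <= horizon]))
  km <- censoringKM(t, d)
  wEvent <- ifelse(d == 1, 1 / km$Gminus(t), NA_real_)
  auc <- vapply(grid, function(tt) {
    caseIdx <- which(t <= tt & d == 1)
    ctrlIdx <- which(t > tt)
    if (length(caseIdx) == 0 || length(ctrlIdx) == 0) return(NA_real_)
    wc <- wEvent[caseIdx]
    wk <- rep(1 / km$G(tt), length(ctrlIdx))
    cmpLess <- outer(s[caseIdx], s[ctrlIdx], "<")  # case scored lower: correct
    cmpEq <- outer(s[caseIdx], s[ctrlIdx], "==")
    W <- wc %o% wk
    sum(W * (cmpLess + 0.5 * cmpEq)) / sum(W)
  }, numeric(1))
  keep <- !is.na(auc)
  if (!all(keep))
    warning(sprintf("dropped %d grid time(s) with no cases or no controls",
                    sum(!keep)))
  curve <- data.frame(time = grid[keep], auc = auc[keep])
  iauc <- if (nrow(curve) >= 2) {
    dt <- diff(curve$time)
    sum(dt * (utils::head(curve$auc, -1) + utils::tail(curve$auc, -1)) / 2) /
      (max(curve$time) - min(curve$time))
  } else if (nrow(curve) == 1) curve$auc else NA_real_
  list(curve = curve, iauc = iauc)
}

#' Compare two IAUCs by a paired one-sided signed-rank test
#'
#' One-sided Wilcoxon signed-rank test of H1: the first AUC(t) series
#' exceeds the second, evaluated at the same grid times (the paired
#' "IAUC1 > IAUC2" comparison).
#'
#' @param aucSeries1,aucSeries2 data.frames `time`, `auc` on identical
#'   grids (from [tdAucCurve])
#' @return one-sided p-value
#' @export
compareIauc <- function(aucSeries1, aucSeries2) {
  if (!isTRUE(all.equal(aucSeries1$time, aucSeries2$time)))
    stop("AUC series must share the same time grid")
  diffs <- aucSeries1$auc - aucSeries2$auc
  if (all(diffs == 0)) return(0.5)
  suppressWarnings(
    stats::wilcox.test(aucSeries1$auc, aucSeries2$auc, paired = TRUE,
                       alternative = "greater")$p.value)
}

#' Logrank test across risk groups
#'
#' At each event time the observed and expected events per group are
#' tallied under the pooled-risk null; the statistic is
#' `chi2 = sum_g (O_g - E_g)^2 / E_g` on m - 1 degrees of freedom, with a
#' two-sided p-value from the chi-squared distribution. Expected counts
#' are computed via the pooled Nelson-Aalen identity
#' `E_g = sum_{i in g} H(T_i)`, algebraically equal to the per-event-time
#' O/E tally.
#'
#' @param groups per-patient group labels (>= 2 non-empty groups)
#' @param outcome data.frame(time, status)
#' @return list with `chi2`, `p`, `df`, `observed`, `expected`
#' @export
logrankTest <- function(groups, outcome) {
  checkOutcome(outcome)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups")
  H <- nelsonAalenAtOwnTime(outcome$time, outcome$status)
  O <- tapply(outcome$status, g, sum)
  E <- tapply(H, g, sum)
  chi2 <- sum((O - E)^2 / E)
  df <- nlevels(g) - 1
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       df = df, observed = as.numeric(O), expected = as.numeric(E))
}

#' Nagelkerke's pseudo R-squared
#'
#' `R^2 = 1 - exp(-(2/n) * (l_model - l_null))`, built on the
#' likelihood-ratio statistic of a fitted Cox model against the null.
#' Note that under censoring this measure shrinks with the censoring
#' fraction; it is reported uncorrected.
#'
#' @param loglikModel,loglikNull maximized and null partial log-likelihoods
#' @param n sample size
#' @return pseudo R-squared
#' @export
nagelkerkeR2 <- function(loglikModel, loglikNull, n) {
  stopifnot(n > 0)
  if (loglikModel < loglikNull - 1e-6)
    stop("model log-likelihood below the null beyond tolerance")
  1 - exp(-(2 / n) * (loglikModel - loglikNull))
}

#' IPCW Brier score at a horizon
#'
#' Inverse-probability-of-censoring-weighted mean squared error of
#' predicted survival probabilities at `tStar`: patients with an event
#' before `tStar` contribute `(0 - S)^2 / G(T_i-)`, patients still at risk
#' past `tStar` contribute `(1 - S)^2 / G(tStar)`, patients censored
#' before `tStar` get weight 0; `G` is the Kaplan-Meier estimate of the
#' censoring distribution and the sum is normalized by the cohort size.
#'
#' @param predictedSurvival per-patient predicted S(tStar)
#' @param outcome data.frame(time, status)
#' @param tStar evaluation horizon (years)
#' @return Brier score in [0, 1]
#' @export
brierScore <- function(predictedSurvival, outcome, tStar) {
  checkOutcome(outcome)
  S <- as.numeric(predictedSurvival)
  t <- outcome$time
  d <- outcome$status
  stopifnot(length(S) == length(t))
  km <- censoringKM(t, d)
  contrib <- numeric(length(t))
  isEvent <- t <= tStar & d == 1
  atRisk <- t > tStar
  gE <- km$Gminus(t[isEvent])
  gR <- km$G(tStar)
  if (any(gE == 0) || (any(atRisk) && gR == 0)) {
    warning("censoring survival reaches 0 at a needed time; dropping terms")
    bad <- which(isEvent)[gE == 0]
    isEvent[bad] <- FALSE
    gE <- gE[gE > 0]
    if (gR == 0) atRisk[] <- FALSE
  }
  contrib[isEvent] <- (0 - S[isEvent])^2 / gE
  contrib[atRisk] <- (1 - S[atRisk])^2 / gR
  sum(contrib) / length(t)
}

#' Signature Skill Score
#'
#' `SSS = (<BS>_random - BS) / <BS>_random`: the relative improvement of a
#' signature's Brier score over the mean Brier score of randomly sampled
#' same-size signatures. 0 means no improvement over random selections;
#' 0.6 means a 60% improvement.
#'
#' @param bs the signature's Brier score
#' @param referenceBs numeric vector of random-signature Brier scores
#' @return the skill score (<= 1; negative = worse than random)
#' @export
signatureSkillScore <- function(bs, referenceBs) {
  if (length(referenceBs) == 0) stop("reference Brier list is empty")
  m <- mean(referenceBs)
  if (!is.finite(m) || m <= 0) stop("reference mean Brier must be > 0")
  (m - bs) / m
}

#' Calibration curve, MAE and Q(0.9)
#'
#' Groups patients into quantile bins of predicted S(tStar); the observed
#' survivor fraction per bin is the within-bin Kaplan-Meier estimate at
#' tStar. Reports the per-bin (mean predicted, observed) curve, the mean
#' absolute error across bins, the 0.9 quantile of the per-bin absolute
#' errors (90% of errors lie within [0, Q(0.9)]), and the range of
#' predicted probabilities.
#'
#' @param predictedSurvival per-patient predicted S(tStar)
#' @param outcome data.frame(time, status)
#' @param tStar evaluation horizon (years)
#' @param nBins number of quantile bins (>= 3; default 10); degenerate
#'   bins are merged with a warning
#' @return list with `curve`, `mae`, `q90`, `range`
#' @export
calibrationAssess <- function(predictedSurvival, outcome, tStar,
                              nBins = 10) {
  checkOutcome(outcome)
  stopifnot(nBins >= 3)
  S <- as.numeric(predictedSurvival)
  qs <- stats::quantile(S, probs = seq(0, 1, length.out = nBins + 1))
  qs <- unique(qs)
  if (length(qs) < 3) stop("predictions too degenerate to bin")
  bins <- cut(S, qs, include.lowest = TRUE)
  kmAt <- function(idx) {
    if (!any(outcome$time[idx] >= tStar) && all(outcome$status[idx] == 1))
      return(NA_real_)
    sf <- survival::survfit(
      survival::Surv(outcome$time[idx], outcome$status[idx]) ~ 1)
    s <- summary(sf, times = tStar, extend = TRUE)$surv
    if (length(s)) s else NA_real_
  }
  idxByBin <- split(seq_along(S), bins)
  # merge bins whose at-risk set dies out before tStar
  obs <- vapply(idxByBin, kmAt, numeric(1))
  pred <- vapply(idxByBin, function(i) mean(S[i]), numeric(1))
  n <- vapply(idxByBin, length, numeric(1))
  if (anyNA(obs)) {
    warning("merging calibration bin(s) with no at-risk patients at tStar")
    while (anyNA(obs) && length(obs) > 1) {
      i <- which(is.na(obs))[1]
      j <- if (i == 1) 2 else i - 1
      idxByBin[[j]] <- c(idxByBin[[j]], idxByBin[[i]])
      idxByBin[[i]] <- NULL
      obs <- vapply(idxByBin, kmAt, numeric(1))
      pred <- vapply(idxByBin, function(i) mean(S[i]), numeric(1))
      n <- vapply(idxByBin, length, numeric(1))
    }
  }
  err <- abs(obs - pred)
  list(curve = data.frame(predicted = unname(pred), observed = unname(obs),
                          n = unname(n)),
       mae = mean(err),
       q90 = unname(stats::quantile(err, 0.9)),
       range = range(S))
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of feature
#' j on all others; exact collinearity is reported as `Inf`.
#'
#' @param design a [SignatureDesign-class] or numeric matrix (>= 2 columns)
#' @return named numeric vector of VIFs
#' @export
vif <- function(design) {
  X <- if (is(design, "SignatureDesign")) design@values else as.matrix(design)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 features")
  if (nrow(X) <= p) stop("need more observations than features")
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(res^2) / tot
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) -> out
  names(out) <- colnames(X)
  out
}
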