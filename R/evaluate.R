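# Assembling the full MetricReport for one signature, and the
# random-signature reference distribution behind the Signature Skill Score.

#' Evaluate a fitted signature on a cohort
#'
#' Computes the full metric suite from a fit and its risk predictions on
#' an evaluation cohort: C-index and IPCW AUC(t)/IAUC of the (negated)
#' linear predictor, the logrank test of the median-split risk groups,
#' the IPCW Brier score and calibration at the horizon, and - when the
#' evaluated cohort is the training cohort - Nagelkerke's pseudo
#' R-squared from the fit's likelihood ratio.
#'
#' @param fit a [CoxSignatureFit-class]
#' @param design the evaluation cohort's [SignatureDesign-class],
#'   standardized with the training stats
#' @param outcome data.frame(time, status) of the evaluation cohort
#' @param horizon evaluation horizon in years (default 10); the outcome is
#'   truncated there
#' @param nBins calibration bins (default 10)
#' @param isTraining when `TRUE`, report Nagelkerke's R-squared from the
#'   fit (only meaningful on the cohort the model was fitted to)
#' @return a [MetricReport-class]
#' @export
evaluateSignature <- function(fit, design, outcome, horizon = 10,
                              nBins = 10, isTraining = FALSE) {
  outcome <- truncateOutcome(checkOutcome(outcome), horizon)
  pred <- predictRisk(fit, design,
                      timeGrid = sort(unique(c(
                        outcome$time[outcome$status == 1], horizon))))
  survScore <- -pred@linearPredictor
  cIdx <- concordanceIndex(survScore, outcome)
  aucRes <- tdAucCurve(survScore, outcome, horizon = horizon)
  sAtH <- pred@survivalCurves[, match(horizon, pred@timeGrid)]
  bs <- brierScore(sAtH, outcome, horizon)
  cal <- calibrationAssess(sAtH, outcome, horizon, nBins = nBins)
  medSplit <- pred@relativeHazard > stats::median(pred@relativeHazard)
  lr <- logrankTest(ifelse(medSplit, "high", "low"), outcome)
  r2 <- if (isTraining) {
    nagelkerkeR2(fit@loglikModel, fit@loglikNull, fit@n)
  } else NA_real_
  new("MetricReport", cIndex = cIdx, aucCurve = aucRes$curve,
      iauc = aucRes$iauc, logrankChi2 = lr$chi2, logrankP = lr$p,
      logrankDf = lr$df, r2Nagelkerke = r2, brier = bs, sss = NA_real_,
      calibration = cal, horizon = horizon)
}

#' Random-signature reference distribution
#'
#' Draws seeded random same-size signatures, fits each on the training
#' cohort and evaluates it on the test cohort, returning the list of
#' [MetricReport-class]s whose Brier scores form the Signature Skill
#' Score's reference mean.
#'
#' @param trainCohort,testCohort [SignatureCohort-class] pair
#' @param k signature size (default 15)
#' @param nRandom number of random signatures (default 100)
#' @param seed integer seed
#' @param exclude optional gene sets the draws must avoid
#' @param horizon evaluation horizon (years)
#' @return list with `reports` (per-signature [MetricReport-class]s,
#'   failed fits carried as `NULL` with a warning), `brier` (vector of
#'   Brier scores) and `iauc`
#' @export
randomReference <- function(trainCohort, testCohort, k = 15, nRandom = 100,
                            seed = 1, exclude = NULL, horizon = 10) {
  pool <- rownames(trainCohort)
  outTrain <- survOutcome(trainCohort, horizon = horizon)
  outTest <- survOutcome(testCohort, horizon = horizon)
  reports <- vector("list", nRandom)
  for (i in seq_len(nRandom)) {
    sig <- sampleRandomSignature(pool, k, seed = childSeed(seed, i),
                                 exclude = exclude,
                                 name = sprintf("Random%03d", i))
    rep_i <- tryCatch({
      dTrain <- assembleDesignMatrix(trainCohort, sig)
      fit <- fitCox(dTrain, outTrain)
      dTest <- assembleDesignMatrix(testCohort, sig,
                                    standardization = dTrain)
      evaluateSignature(fit, dTest, outTest, horizon = horizon)
    }, error = function(e) {
      warning(sprintf("random signature %d failed: %s", i,
                      conditionMessage(e)))
      NULL
    })
    reports[[i]] <- rep_i
  }
  ok <- !vapply(reports, is.null, logical(1))
  list(reports = reports,
       brier = vapply(reports[ok], function(r) r@brier, numeric(1)),
       iauc = vapply(reports[ok], function(r) r@iauc, numeric(1)))
}
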