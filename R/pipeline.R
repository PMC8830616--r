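# End-to-end orchestration of the study design on synthetic or
# user-supplied cohorts.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: the cohort source (file
#' paths or a [syntheticConfig]), the train/test split, the signature
#' roster, screening, evaluation, stratification and the random-signature
#' reference. Every stochastic stage has its own seed derived from
#' `seed`.
#'
#' @param synthetic a [syntheticConfig] (used when `exprPath` is `NULL`)
#' @param exprPath,clinPath cohort file paths (override `synthetic`)
#' @param trainFraction train split fraction (default 0.7)
#' @param filters named list passed to [filterCohort] (default: none)
#' @param signatures named list of [GeneSignature-class] to evaluate
#'   (default: a seeded random roster built at run time)
#' @param nRosterRandom when `signatures` is `NULL`, how many random
#'   15-gene signatures to put on the roster (default 5, plus NPI)
#' @param buildHybrid run [sisSelect] on the training set and add the
#'   selected hybrid signature to the roster (default `TRUE`)
#' @param sisVariant,targetSize screening settings
#' @param horizon evaluation horizon in years (default 10)
#' @param nBins calibration bins
#' @param nRandom size of the random-signature reference (default 100)
#' @param alpha,minbucket,maxDepth,B stratification settings
#' @param seed master seed
#' @return a config list of class `"PipelineConfig"`
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           exprPath = NULL, clinPath = NULL,
                           trainFraction = 0.7, filters = list(),
                           signatures = NULL, nRosterRandom = 5,
                           buildHybrid = TRUE,
                           sisVariant = "vanilla", targetSize = 15,
                           horizon = 10, nBins = 10, nRandom = 100,
                           alpha = 0.05, minbucket = NULL, maxDepth = 4,
                           B = 499, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full signature-benchmarking pipeline
#'
#' Executes: load/generate -> filter -> split -> (screen the hybrid
#' signature on the training set) -> per-signature Cox fit on the
#' training set -> predictions and metric reports on the test set ->
#' risk-group stratification per signature -> best-group intersection and
#' agreement profile -> random-signature reference and Signature Skill
#' Scores. When `outDir` is given, reports are written as CSV/JSON.
#'
#' @param config a [pipelineConfig]
#' @param outDir optional output directory for CSV/JSON reports
#' @return a report bundle: list with `roster`, `fits`, `trainReports`,
#'   `testReports` (with SSS filled in), `stratifications`,
#'   `intersections`, `agreement`, `reference`, `seeds`, `cohorts`
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  seeds <- list(split = childSeed(config$seed, "split"),
                roster = childSeed(config$seed, "roster"),
                sis = childSeed(config$seed, "sis"),
                reference = childSeed(config$seed, "reference"),
                strat = childSeed(config$seed, "strat"))

  cohort <- if (!is.null(config$exprPath)) {
    readCohort(config$exprPath, config$clinPath)
  } else {
    generateCohort(config$synthetic)$cohort
  }
  if (length(config$filters))
    cohort <- do.call(filterCohort, c(list(cohort), config$filters))

  parts <- splitCohort(cohort, config$trainFraction, seed = seeds$split)
  train <- parts$train
  test <- parts$test
  outTrain <- survOutcome(train, horizon = config$horizon)
  outTest <- survOutcome(test, horizon = config$horizon)

  roster <- config$signatures
  if (is.null(roster)) {
    roster <- lapply(seq_len(config$nRosterRandom), function(i)
      sampleRandomSignature(rownames(cohort), config$targetSize,
                            seed = childSeed(seeds$roster, i),
                            name = sprintf("Random%d", i)))
    names(roster) <- vapply(roster, function(s) s@name, character(1))
    roster$NPI <- geneSignature("NPI", includesNPI = TRUE)
  }
  if (config$buildHybrid) {
    allSig <- geneSignature("all", rownames(train), includesNPI = TRUE)
    fullDesign <- assembleDesignMatrix(train, allSig)
    scr <- sisSelect(fullDesign, outTrain, targetSize = config$targetSize,
                     variant = config$sisVariant, seed = seeds$sis,
                     signatureName = "Hybrid")
    roster <- c(list(Hybrid = scr@selected), roster)
  } else scr <- NULL

  fits <- list(); trainReports <- list(); testReports <- list()
  strats <- list(); bestSets <- list(); predMaps <- list()
  for (nm in names(roster)) {
    sig <- roster[[nm]]
    dTrain <- assembleDesignMatrix(train, sig)
    fit <- fitCox(dTrain, outTrain)
    dTest <- assembleDesignMatrix(test, sig, standardization = dTrain)
    fits[[nm]] <- fit
    trainReports[[nm]] <- evaluateSignature(fit, dTrain, outTrain,
                                            horizon = config$horizon,
                                            nBins = config$nBins,
                                            isTraining = TRUE)
    testReports[[nm]] <- evaluateSignature(fit, dTest, outTest,
                                           horizon = config$horizon,
                                           nBins = config$nBins)
    pred <- predictRisk(fit, dTest,
                        timeGrid = c(outTest$time[outTest$status == 1],
                                     config$horizon))
    strat <- partitionRiskGroups(pred@relativeHazard, outTest,
                                 alpha = config$alpha,
                                 minbucket = config$minbucket,
                                 maxDepth = config$maxDepth, B = config$B,
                                 seed = childSeed(seeds$strat, nm))
    strats[[nm]] <- strat
    bestSets[[nm]] <- colnames(test)[strat@groups == 1L]
    sAtH <- pred@survivalCurves[, match(config$horizon, pred@timeGrid)]
    names(sAtH) <- colnames(test)
    predMaps[[nm]] <- sAtH
  }

  reference <- randomReference(train, test, k = config$targetSize,
                               nRandom = config$nRandom,
                               seed = seeds$reference,
                               exclude = lapply(roster, function(s)
                                 s@features),
                               horizon = config$horizon)
  for (nm in names(testReports))
    testReports[[nm]]@sss <- signatureSkillScore(testReports[[nm]]@brier,
                                                 reference$brier)

  intersections <- intersectBestGroups(bestSets, outTest,
                                       horizon = config$horizon)
  agreement <- agreementProfile(predMaps)

  bundle <- list(roster = roster, screening = scr, fits = fits,
                 trainReports = trainReports, testReports = testReports,
                 stratifications = strats, intersections = intersections,
                 agreement = agreement, reference = reference,
                 seeds = seeds,
                 cohorts = list(train = train, test = test))
  if (!is.null(outDir)) writeBundle(bundle, outDir, config)
  bundle
}

# Serialize the report bundle as CSV/JSON.
writeBundle <- function(bundle, outDir, config) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  metricRow <- function(r, nm) {
    data.frame(signature = nm, c_index = r@cIndex, iauc = r@iauc,
               sss = r@sss, r2_nagelkerke = r@r2Nagelkerke,
               brier = r@brier, logrank_chi2 = r@logrankChi2,
               logrank_p = r@logrankP, cal_mae = r@calibration$mae,
               cal_q90 = r@calibration$q90)
  }
  writeTab <- function(reports, file) {
    tab <- do.call(rbind, lapply(names(reports), function(nm)
      metricRow(reports[[nm]], nm)))
    utils::write.csv(format(tab, digits = 10), file.path(outDir, file),
                     row.names = FALSE, quote = FALSE)
  }
  writeTab(bundle$trainReports, "metrics_train.csv")
  writeTab(bundle$testReports, "metrics_test.csv")
  for (nm in names(bundle$fits))
    utils::write.csv(format(coxTable(bundle$fits[[nm]]), digits = 10),
                     file.path(outDir, sprintf("cox_%s.csv",
                                               gsub("[^A-Za-z0-9]", "_", nm))),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(format(bundle$intersections, digits = 10),
                   file.path(outDir, "intersections.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seeds = bundle$seeds,
         sss = lapply(bundle$testReports, function(r) r@sss),
         referenceBrierMean = mean(bundle$reference$brier)),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
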