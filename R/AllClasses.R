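#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

#' SignatureCohort: expression + clinical + censored survival outcome
#'
#' A `SignatureCohort` couples a log2-normalized gene expression matrix
#' (genes x samples, assay `"exprs"`) with per-sample clinical covariates
#' and a right-censored survival outcome, kept aligned by sample ID in the
#' `colData`. It extends [SummarizedExperiment::SummarizedExperiment] so all
#' the usual subsetting and accessor machinery applies.
#'
#' Mandatory `colData` columns are `time_years` (follow-up, years, > 0) and
#' `status` (1 = event, 0 = censored). Optional clinical columns follow the
#' package's clinical CSV schema: `er`, `her2`, `chemo` (`"pos"/"neg"`,
#' `"yes"/"no"`), `age`, `tumor_size_cm`, `node_stage` (1-3), `grade` (1-3)
#' and `npi` (computable from the last three via [computeNPI]).
#'
#' @slot endpointKind single string, `"disease_specific"` or `"overall"`.
#' @seealso [makeCohort], [readCohort], [generateCohort]
#' @export
setClass("SignatureCohort",
  contains = "SummarizedExperiment",
  representation(endpointKind = "character"),
  prototype(endpointKind = "disease_specific")
)

setValidity("SignatureCohort", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("time_years", "status") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'time_years' and 'status'")
  else {
    tm <- cd$time_years
    st <- cd$status
    if (any(!is.finite(tm)) || any(tm <= 0))
      msg <- c(msg, "all survival times must be finite and > 0")
    if (!all(st %in% c(0, 1)))
      msg <- c(msg, "status must be 0/1")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs must be present and unique")
  if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
    msg <- c(msg, "gene symbols must be unique (collapse probes first)")
  if (!object@endpointKind %in% c("disease_specific", "overall"))
    msg <- c(msg, "endpointKind must be 'disease_specific' or 'overall'")
  for (col in c("node_stage", "grade")) {
    if (col %in% colnames(cd)) {
      v <- cd[[col]]
      if (!all(is.na(v) | (v %in% 1:3)))
        msg <- c(msg, sprintf("'%s' must be an ordinal in 1..3", col))
    }
  }
  if (length(msg)) msg else TRUE
})

#' GeneSignature: a named, ordered feature list
#'
#' A prognostic signature is an ordered list of unique gene symbols,
#' optionally augmented with the Nottingham Prognostic Index (NPI) treated
#' as a pseudo-gene feature (`includesNPI`). The NPI-only signature has an
#' empty gene list and `includesNPI = TRUE`.
#'
#' @slot name single string.
#' @slot features character vector of unique gene symbols (possibly empty).
#' @slot includesNPI logical flag.
#' @seealso [builtinSignatures], [sampleRandomSignature]
#' @export
setClass("GeneSignature",
  representation(name = "character", features = "character",
                 includesNPI = "logical"),
  prototype(name = "signature", features = character(), includesNPI = FALSE)
)

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (anyDuplicated(object@features)) msg <- c(msg, "features must be unique")
  if ("NPI" %in% object@features)
    msg <- c(msg, "NPI enters via includesNPI, not the gene list")
  if (length(object@features) == 0L && !isTRUE(object@includesNPI))
    msg <- c(msg, "empty signature is only valid with includesNPI = TRUE")
  if (length(msg)) msg else TRUE
})

#' SignatureDesign: standardized per-sample covariate matrix
#'
#' Samples x features matrix assembled from a cohort and a
#' [GeneSignature]: each column is a gene's expression row (plus an `NPI`
#' column when the signature includes it), z-scored either with its own
#' mean/sd (`standardization = "fit"`) or with reference (training) stats.
#'
#' @slot values numeric matrix, samples x features; no missing values.
#' @slot center,scale named numeric vectors used for standardization.
#' @export
setClass("SignatureDesign",
  representation(values = "matrix", center = "numeric", scale = "numeric")
)

setValidity("SignatureDesign", function(object) {
  msg <- character()
  v <- object@values
  if (anyNA(v)) msg <- c(msg, "design matrix must not contain missing values")
  if (is.null(colnames(v))) msg <- c(msg, "design columns must be named")
  if (!identical(colnames(v), names(object@center)) ||
      !identical(colnames(v), names(object@scale)))
    msg <- c(msg, "center/scale names must match column order")
  if (length(msg)) msg else TRUE
})

#' CoxSignatureFit: a fitted proportional-hazards model for one signature
#'
#' Wraps the maximum-partial-likelihood fit (Efron ties) with Wald
#' intervals, both log-likelihoods (for the likelihood-ratio statistic and
#' Nagelkerke's pseudo R-squared) and the Breslow baseline cumulative
#' hazard needed for absolute survival predictions.
#'
#' @slot coefficients named numeric, log hazard ratios.
#' @slot hazardRatios exp(coefficients).
#' @slot ci95 features x 2 matrix (`lower`, `upper`) on the HR scale.
#' @slot pValues Wald p-values.
#' @slot loglikModel,loglikNull maximized and null partial log-likelihoods.
#' @slot n,nEvents sample and event counts.
#' @slot baselineCumhaz data.frame `time`, `hazard`: Breslow baseline
#'   cumulative hazard at covariates 0 (i.e. at the standardization center).
#' @export
setClass("CoxSignatureFit",
  representation(coefficients = "numeric", hazardRatios = "numeric",
                 ci95 = "matrix", pValues = "numeric",
                 loglikModel = "numeric", loglikNull = "numeric",
                 n = "integer", nEvents = "integer",
                 baselineCumhaz = "data.frame")
)

setValidity("CoxSignatureFit", function(object) {
  msg <- character()
  if (any(abs(object@hazardRatios - exp(object@coefficients)) >
          1e-8 * (1 + object@hazardRatios)))
    msg <- c(msg, "hazardRatios must equal exp(coefficients)")
  if (object@loglikModel < object@loglikNull - 1e-8)
    msg <- c(msg, "model log-likelihood cannot fall below the null")
  if (length(msg)) msg else TRUE
})

#' RiskPredictions: per-patient risk from a fitted signature model
#'
#' @slot linearPredictor named numeric, x %*% beta-hat.
#' @slot relativeHazard exp(lp - mean lp); per-patient hazard ratio
#'   relative to the cohort-average covariate profile.
#' @slot survivalCurves patients x time-grid matrix of S(t | x).
#' @slot timeGrid numeric vector of evaluation times (years).
#' @export
setClass("RiskPredictions",
  representation(linearPredictor = "numeric", relativeHazard = "numeric",
                 survivalCurves = "matrix", timeGrid = "numeric")
)

setValidity("RiskPredictions", function(object) {
  msg <- character()
  sc <- object@survivalCurves
  if (ncol(sc) != length(object@timeGrid))
    msg <- c(msg, "survivalCurves columns must match timeGrid")
  if (length(sc) && (min(sc) < -1e-12 || max(sc) > 1 + 1e-12))
    msg <- c(msg, "survival probabilities must lie in [0, 1]")
  if (ncol(sc) > 1 && any(sc[, -1, drop = FALSE] >
                          sc[, -ncol(sc), drop = FALSE] + 1e-12))
    msg <- c(msg, "S(t) must be non-increasing in t")
  if (length(msg)) msg else TRUE
})

#' ScreeningResult: output of (iterative) sure independence screening
#'
#' @slot ranked data.frame with `feature`, `utility` (marginal partial-
#'   log-likelihood gain), `selected`, `iteration`.
#' @slot selected the selected [GeneSignature].
#' @slot iterations number of ISIS iterations run.
#' @slot variant `"vanilla"` or `"aggressive"`.
#' @export
setClass("ScreeningResult",
  representation(ranked = "data.frame", selected = "GeneSignature",
                 iterations = "integer", variant = "character")
)

#' MetricReport: the full evaluation suite for one signature on one cohort
#'
#' @slot cIndex Harrell's concordance (pair formula; prediction ties 1/2).
#' @slot aucCurve data.frame `time`, `auc`: IPCW cumulative/dynamic AUC(t).
#' @slot iauc trapezoidal mean of AUC(t) over the event-time grid.
#' @slot logrankChi2,logrankP,logrankDf logrank test of the median-split
#'   risk groups (reported for a single continuous score).
#' @slot r2Nagelkerke Nagelkerke's pseudo R-squared (NA on test sets,
#'   where no model is refitted).
#' @slot brier IPCW Brier score at the horizon.
#' @slot sss Signature Skill Score vs the random-signature reference
#'   (NA until a reference is supplied).
#' @slot calibration list: `curve` (per-bin predicted/observed), `mae`,
#'   `q90`, `range` of predicted probabilities.
#' @slot horizon evaluation horizon in years.
#' @export
setClass("MetricReport",
  representation(cIndex = "numeric", aucCurve = "data.frame", iauc = "numeric",
                 logrankChi2 = "numeric", logrankP = "numeric",
                 logrankDf = "numeric", r2Nagelkerke = "numeric",
                 brier = "numeric", sss = "numeric", calibration = "list",
                 horizon = "numeric")
)

#' RiskStratification: permutation-significance recursive partition
#'
#' Leaves ("nodes") are contiguous intervals of the hazard score, numbered
#' by increasing risk: Node 1 is the best-prognosis group.
#'
#' @slot thresholds ordered split points on the hazard score.
#' @slot groups integer node label per patient (1 = best prognosis).
#' @slot splitPValues permutation p-value of each accepted split.
#' @slot nodeSizes,nodeEvents per-node patient and event counts.
#' @export
setClass("RiskStratification",
  representation(thresholds = "numeric", groups = "integer",
                 splitPValues = "numeric", nodeSizes = "integer",
                 nodeEvents = "integer")
)

setValidity("RiskStratification", function(object) {
  msg <- character()
  k <- length(object@thresholds) + 1L
  if (!all(object@groups %in% seq_len(k)))
    msg <- c(msg, "group labels must index the leaf intervals")
  if (is.unsorted(object@thresholds, strictly = TRUE) &&
      length(object@thresholds) > 1)
    msg <- c(msg, "thresholds must be strictly increasing")
  if (length(msg)) msg else TRUE
})
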