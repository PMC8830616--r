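#' Construct a SignatureCohort from its parts
#'
#' Assembles an expression matrix, a clinical table and a survival outcome
#' into a validated [SignatureCohort-class]. Alignment is by sample ID,
#' never by position: the clinical table's `sample_id` order defines the
#' cohort order and the expression columns are matched to it.
#'
#' @param exprs numeric matrix, genes x samples; unique rownames (gene
#'   symbols) and colnames (sample IDs).
#' @param clinical data.frame with a `sample_id` column plus the clinical
#'   CSV schema columns (`time_years`, `status`, and optionally `er`,
#'   `her2`, `chemo`, `age`, `tumor_size_cm`, `node_stage`, `grade`, `npi`).
#' @param endpointKind `"disease_specific"` (default) or `"overall"`.
#' @return a [SignatureCohort-class]
#' @export
makeCohort <- function(exprs, clinical, endpointKind = "disease_specific") {
  stopifnot(is.matrix(exprs), is.data.frame(clinical),
            "sample_id" %in% colnames(clinical))
  ids <- as.character(clinical$sample_id)
  if (anyDuplicated(ids)) stop("duplicate sample IDs in clinical table")
  common <- intersect(ids, colnames(exprs))
  if (length(common) == 0L)
    stop("no sample IDs shared between expression and clinical data")
  dropped <- setdiff(union(ids, colnames(exprs)), common)
  if (length(dropped))
    warning(sprintf("dropping %d samples absent from one input (e.g. %s)",
                    length(dropped), dropped[1]))
  keep <- ids[ids %in% common]
  cd <- clinical[match(keep, ids), setdiff(colnames(clinical), "sample_id"),
                 drop = FALSE]
  rownames(cd) <- keep
  se <- SummarizedExperiment(
    assays = list(exprs = exprs[, keep, drop = FALSE]),
    colData = DataFrame(cd)
  )
  new("SignatureCohort", se, endpointKind = endpointKind)
}

#' @describeIn makeCohort expression matrix accessor (genes x samples)
#' @param cohort a [SignatureCohort-class]
#' @export
exprsMatrix <- function(cohort) assay(cohort, "exprs")

#' Survival outcome of a cohort
#'
#' Returns the right-censored outcome as a data.frame with columns `time`
#' and `status` and sample IDs as rownames. With a finite `horizon`,
#' follow-up past the horizon is administratively censored there (the
#' package's analyses use a 10-year disease-specific horizon).
#'
#' @param cohort a [SignatureCohort-class]
#' @param horizon optional truncation time in years (default `NULL`: none)
#' @return data.frame(time, status)
#' @export
survOutcome <- function(cohort, horizon = NULL) {
  cd <- colData(cohort)
  out <- data.frame(time = as.numeric(cd$time_years),
                    status = as.numeric(cd$status),
                    row.names = colnames(cohort))
  truncateOutcome(out, horizon)
}

#' NPI scores of a cohort
#'
#' Uses the stored `npi` column when present, otherwise computes it from
#' `tumor_size_cm`, `node_stage` and `grade` via [computeNPI].
#'
#' @param cohort a [SignatureCohort-class]
#' @return named numeric vector
#' @export
npiScores <- function(cohort) {
  cd <- colData(cohort)
  if ("npi" %in% colnames(cd)) {
    npi <- as.numeric(cd$npi)
  } else {
    needed <- c("tumor_size_cm", "node_stage", "grade")
    if (!all(needed %in% colnames(cd)))
      stop("cohort has neither an 'npi' column nor ",
           "tumor_size_cm/node_stage/grade to compute it")
    npi <- computeNPI(cd$tumor_size_cm, cd$node_stage, cd$grade)
  }
  names(npi) <- colnames(cohort)
  npi
}

setMethod("show", "SignatureCohort", function(object) {
  cat("SignatureCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  out <- survOutcome(object)
  cat(sprintf("  endpoint: %s; events: %d/%d (%.1f%%)\n",
              object@endpointKind, sum(out$status), nrow(out),
              100 * mean(out$status)))
  extra <- setdiff(colnames(colData(object)), c("time_years", "status"))
  if (length(extra))
    cat("  clinical columns:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s': %d genes%s\n", object@name,
              length(object@features),
              if (object@includesNPI) " + NPI" else ""))
  if (length(object@features))
    cat("  ", paste(utils::head(object@features, 8), collapse = ", "),
        if (length(object@features) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "CoxSignatureFit", function(object) {
  cat(sprintf("CoxSignatureFit: %d features, n = %d (%d events)\n",
              length(object@coefficients), object@n, object@nEvents))
  tab <- coxTable(object)
  print(utils::head(tab, 10), digits = 3)
  if (nrow(tab) > 10) cat("  ...\n")
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf(paste0("MetricReport (horizon %.0fy): C = %.3f, IAUC = %.3f, ",
                     "Brier = %.3f, SSS = %s\n"),
              object@horizon, object@cIndex, object@iauc, object@brier,
              ifelse(is.na(object@sss), "NA", sprintf("%.3f", object@sss))))
  cat(sprintf("  logrank chi2 = %.2f (p = %.3g), R2 = %s, cal MAE = %.3f\n",
              object@logrankChi2, object@logrankP,
              ifelse(is.na(object@r2Nagelkerke), "NA",
                     sprintf("%.3f", object@r2Nagelkerke)),
              object@calibration$mae))
})

setMethod("show", "RiskStratification", function(object) {
  k <- length(object@nodeSizes)
  cat(sprintf("RiskStratification: %d risk group%s\n", k,
              if (k == 1) "" else "s"))
  for (i in seq_len(k))
    cat(sprintf("  Node %d: n = %d, events = %d\n", i,
                object@nodeSizes[i], object@nodeEvents[i]))
  if (length(object@thresholds))
    cat("  thresholds:",
        paste(signif(object@thresholds, 4), collapse = ", "), "\n")
})

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("ScreeningResult (%s, %d iteration%s): %d features selected\n",
              object@variant, object@iterations,
              if (object@iterations == 1) "" else "s",
              length(object@selected@features) +
                as.integer(object@selected@includesNPI)))
  show(object@selected)
})

#' Table-1-style coefficient table of a Cox fit
#'
#' @param fit a [CoxSignatureFit-class]
#' @return data.frame with feature, HR, CI bounds and p-value
#' @export
coxTable <- function(fit) {
  data.frame(feature = names(fit@coefficients),
             HR = unname(fit@hazardRatios),
             ci_lower = unname(fit@ci95[, "lower"]),
             ci_upper = unname(fit@ci95[, "upper"]),
             p_value = unname(fit@pValues),
             row.names = NULL)
}
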