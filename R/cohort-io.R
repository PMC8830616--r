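# Cohort file I/O, probe collapse, filtering, splitting, downsampling.

clinicalMandatory <- c("sample_id", "time_years", "status")

#' Read a cohort from an expression TSV and a clinical CSV
#'
#' The expression file is tab-separated with genes as rows: first column
#' gene symbol, header row of sample IDs (a GEO-series-matrix-like layout).
#' The clinical file is comma-separated with columns
#' `sample_id,time_years,status[,er,her2,chemo,age,tumor_size_cm,node_stage,grade,npi]`.
#' The cohort is restricted to the intersection of sample IDs in
#' clinical-file order; dropped samples are reported with a warning.
#'
#' @param exprPath path to the expression TSV
#' @param clinPath path to the clinical CSV
#' @param endpointKind passed to [makeCohort]
#' @return a [SignatureCohort-class]
#' @export
readCohort <- function(exprPath, clinPath,
                       endpointKind = "disease_specific") {
  expr <- utils::read.delim(exprPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2) stop("expression file needs a gene column + samples")
  genes <- as.character(expr[[1]])
  mat <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(expr[-1], is.numeric, logical(1)))[1]
    cell <- which(is.na(suppressWarnings(as.numeric(expr[[bad + 1]]))))[1]
    stop(sprintf("non-numeric expression value at row %d, column '%s'",
                 cell, colnames(expr)[bad + 1]))
  }
  rownames(mat) <- genes
  clin <- utils::read.csv(clinPath, stringsAsFactors = FALSE)
  missing <- setdiff(clinicalMandatory, colnames(clin))
  if (length(missing))
    stop("clinical file lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  makeCohort(mat, clin, endpointKind = endpointKind)
}

#' Write a cohort to the package's TSV/CSV dialects
#'
#' @param cohort a [SignatureCohort-class]
#' @param exprPath,clinPath output paths
#' @return invisibly, the two paths
#' @export
writeCohort <- function(cohort, exprPath, clinPath) {
  mat <- exprsMatrix(cohort)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(colData(cohort))
  clin <- data.frame(sample_id = colnames(cohort), cd, check.names = FALSE,
                     row.names = NULL)
  utils::write.csv(clin, clinPath, row.names = FALSE, quote = FALSE)
  invisible(c(exprPath, clinPath))
}

#' Collapse probe-level values to one row per gene symbol
#'
#' Probes mapping to the same gene are summarized by their arithmetic
#' per-sample mean (the `limma::avereps` convention used for multi-probe
#' arrays); probes without annotation are removed when
#' `dropUnannotated = TRUE`.
#'
#' @param values numeric matrix, probes x samples, rownames = probe IDs
#' @param probeToGene named character vector, probe ID -> gene symbol;
#'   probes absent from the map (or mapping to `NA`/`""`) are unannotated
#' @param dropUnannotated drop unannotated probes (default `TRUE`); when
#'   `FALSE` they are kept under their probe ID
#' @return numeric matrix, genes x samples
#' @export
collapseProbes <- function(values, probeToGene, dropUnannotated = TRUE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  ids <- probeToGene[rownames(values)]
  unann <- is.na(ids) | ids == ""
  if (dropUnannotated) {
    values <- values[!unann, , drop = FALSE]
    ids <- ids[!unann]
    if (nrow(values) == 0L) stop("no annotated probes left after dropping")
  } else {
    ids[unann] <- rownames(values)[unann]
  }
  out <- limma::avereps(values, ID = as.character(ids))
  out[order(rownames(out)), , drop = FALSE]
}

#' Filter a cohort on clinical criteria
#'
#' Criteria mirror the study's cohort definition: ER-positive,
#' HER2-negative, chemotherapy-naive patients, optionally under an age
#' limit. Per-criterion attrition counts are reported via `message()`.
#'
#' @param cohort a [SignatureCohort-class]
#' @param er,her2,chemo required factor levels (`NULL` = no restriction);
#'   e.g. `er = "pos"`, `her2 = "neg"`, `chemo = "no"`
#' @param ageLt keep patients with `age < ageLt` (`NULL` = no restriction)
#' @return the filtered [SignatureCohort-class], order preserved
#' @export
filterCohort <- function(cohort, er = NULL, her2 = NULL, chemo = NULL,
                         ageLt = NULL) {
  cd <- colData(cohort)
  keep <- rep(TRUE, ncol(cohort))
  step <- function(keep, crit, label) {
    before <- sum(keep)
    keep <- keep & crit
    message(sprintf("filter %s: %d -> %d samples", label, before, sum(keep)))
    keep
  }
  if (!is.null(er))
    keep <- step(keep, !is.na(cd$er) & cd$er == er, paste0("er=", er))
  if (!is.null(her2))
    keep <- step(keep, !is.na(cd$her2) & cd$her2 == her2,
                 paste0("her2=", her2))
  if (!is.null(chemo))
    keep <- step(keep, !is.na(cd$chemo) & cd$chemo == chemo,
                 paste0("chemo=", chemo))
  if (!is.null(ageLt))
    keep <- step(keep, !is.na(cd$age) & cd$age < ageLt,
                 paste0("age<", ageLt))
  if (!any(keep)) stop("no samples satisfy all filter criteria")
  cohort[, keep]
}

#' Random train/test split of a cohort
#'
#' Draws `floor(trainFraction * n)` training samples uniformly at random
#' (reproducibly for a given seed); the remainder is the test set. An
#' optional stratified mode balances the event fraction across the parts.
#'
#' @param cohort a [SignatureCohort-class]
#' @param trainFraction fraction in (0, 1]
#' @param seed integer seed
#' @param stratifyByEvent balance event status across parts (default
#'   `FALSE`: a simple random split)
#' @return list with elements `train` and `test`
#' @export
splitCohort <- function(cohort, trainFraction, seed,
                        stratifyByEvent = FALSE) {
  stopifnot(trainFraction > 0, trainFraction <= 1)
  n <- ncol(cohort)
  nTrain <- floor(trainFraction * n)
  idx <- withSeed(seed, {
    if (stratifyByEvent) {
      st <- survOutcome(cohort)$status
      ev <- which(st == 1)
      ce <- which(st == 0)
      nEv <- round(nTrain * length(ev) / n)
      sort(c(sample(ev, min(nEv, length(ev))),
             sample(ce, min(nTrain - nEv, length(ce)))))
    } else {
      sort(sample(n, nTrain))
    }
  })
  list(train = cohort[, idx],
       test = cohort[, setdiff(seq_len(n), idx)])
}

#' Downsample a cohort to a target event-to-patients-at-risk ratio
#'
#' Draws a random subset of the requested size whose event count equals
#' `round(size * targetEventRatio)`, the scheme used to match an external
#' test cohort to the training cohort's event ratio. Repeated calls with
#' different seeds give replicated downsampled sets.
#'
#' @param cohort a [SignatureCohort-class]
#' @param targetEventRatio desired event fraction in (0, 1)
#' @param size number of samples to draw
#' @param seed integer seed
#' @return a downsampled [SignatureCohort-class]
#' @export
downsampleMatched <- function(cohort, targetEventRatio, size, seed) {
  out <- survOutcome(cohort)
  ev <- which(out$status == 1)
  ce <- which(out$status == 0)
  nEv <- round(size * targetEventRatio)
  nCe <- size - nEv
  if (nEv > length(ev) || nCe > length(ce))
    stop(sprintf(paste0("infeasible downsampling: need %d events and %d ",
                        "non-events, have %d and %d"),
                 nEv, nCe, length(ev), length(ce)))
  idx <- withSeed(seed, sort(c(sample(ev, nEv), sample(ce, nCe))))
  cohort[, idx]
}
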