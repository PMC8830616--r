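# Permutation-significance recursive partitioning of hazard scores,
# Kaplan-Meier reporting, best-group intersection, agreement profiles.

# Max-over-thresholds two-sample logrank statistic for patients sorted by
# score, via martingale residuals: for a left group of the first k sorted
# patients, O - E = cumsum(status - H)[k] and E = cumsum(H)[k] with H the
# pooled Nelson-Aalen hazard at each subject's time.
maxSplitStat <- function(u, H, candidates, D) {
  cu <- cumsum(u)[candidates]
  cE <- cumsum(H)[candidates]
  ok <- cE > 1e-12 & (D - cE) > 1e-12
  stat <- rep(-Inf, length(candidates))
  stat[ok] <- cu[ok]^2 * (1 / cE[ok] + 1 / (D - cE[ok]))
  stat
}

#' Partition a hazard score into risk groups by permutation significance
#'
#' Unbiased recursive partitioning on a single continuous hazard score:
#' within each node, every threshold respecting `minbucket` is scored by
#' the two-sample logrank statistic, and the node is split at the
#' maximizing threshold iff the Monte-Carlo permutation p-value of the
#' maximally selected statistic is below `alpha` (an asymptotic
#' chi-squared(1) option is available). The recursion stops purely on the
#' significance criterion plus `minbucket`/`maxDepth`; no pruning.
#' Resulting nodes are contiguous score intervals, numbered by increasing
#' risk (Node 1 = best prognosis).
#'
#' @param hazardScore per-patient hazard score (higher = higher risk),
#'   e.g. the relative hazard from [predictRisk]
#' @param outcome data.frame(time, status)
#' @param alpha split significance level (default 0.05)
#' @param minbucket minimum node size (default `max(20, 0.05 * n)`)
#' @param maxDepth maximum recursion depth (default 4)
#' @param B Monte-Carlo permutations per split test (default 999)
#' @param seed integer seed for the permutation draws
#' @param pMethod `"permutation"` (default) or `"asymptotic"`
#' @return a [RiskStratification-class]
#' @export
partitionRiskGroups <- function(hazardScore, outcome, alpha = 0.05,
                                minbucket = NULL, maxDepth = 4,
                                B = 999, seed = 1,
                                pMethod = c("permutation", "asymptotic")) {
  pMethod <- match.arg(pMethod)
  checkOutcome(outcome)
  s <- as.numeric(hazardScore)
  n <- length(s)
  stopifnot(n == nrow(outcome))
  if (is.null(minbucket)) minbucket <- max(20, ceiling(0.05 * n))
  if (n < 2 * minbucket || sum(outcome$status) < 2)
    stop("too few patients or events to stratify")

  thresholds <- numeric(0)
  pvals <- numeric(0)
  splitCounter <- 0L

  splitNode <- function(idx, depth) {
    if (length(idx) < 2 * minbucket || depth >= maxDepth) return(NULL)
    t_i <- outcome$time[idx]
    d_i <- outcome$status[idx]
    if (sum(d_i) < 2) return(NULL)
    ord <- order(s[idx])
    si <- s[idx][ord]
    H <- nelsonAalenAtOwnTime(t_i, d_i)[ord]
    u <- d_i[ord] - H
    D <- sum(d_i)
    m <- length(idx)
    cand <- seq(minbucket, m - minbucket)
    cand <- cand[si[cand] < si[cand + 1] - 1e-12]  # real thresholds only
    if (length(cand) == 0) return(NULL)
    obs <- max(maxSplitStat(u, H, cand, D))
    if (!is.finite(obs)) return(NULL)
    p <- if (pMethod == "asymptotic") {
      stats::pchisq(obs, 1, lower.tail = FALSE)
    } else {
      splitCounter <<- splitCounter + 1L
      withSeed(childSeed(seed, splitCounter), {
        exceed <- 0L
        for (b in seq_len(B)) {
          pm <- sample.int(m)
          st <- maxSplitStat(u[pm], H[pm], cand, D)
          if (max(st) >= obs - 1e-12) exceed <- exceed + 1L
        }
        (1 + exceed) / (B + 1)
      })
    }
    if (p >= alpha) return(NULL)
    k <- cand[which.max(maxSplitStat(u, H, cand, D))]
    thr <- (si[k] + si[k + 1]) / 2
    thresholds <<- c(thresholds, thr)
    pvals <<- c(pvals, p)
    left <- idx[s[idx] <= thr]
    right <- idx[s[idx] > thr]
    splitNode(left, depth + 1L)
    splitNode(right, depth + 1L)
    invisible(NULL)
  }

  if (length(unique(s)) > 1) splitNode(seq_len(n), 0L)
  ordThr <- order(thresholds)
  thresholds <- thresholds[ordThr]
  pvals <- pvals[ordThr]
  groups <- findInterval(s, thresholds) + 1L
  k <- length(thresholds) + 1L
  new("RiskStratification",
      thresholds = thresholds, groups = groups, splitPValues = pvals,
      nodeSizes = vapply(seq_len(k), function(g)
        sum(groups == g), integer(1)),
      nodeEvents = vapply(seq_len(k), function(g)
        as.integer(sum(outcome$status[groups == g])), integer(1)))
}

#' Kaplan-Meier curves per risk group with a global logrank test
#'
#' @param stratification a [RiskStratification-class]
#' @param outcome data.frame(time, status), same patients in the same order
#' @param horizon survival-probability report time (default 10 years)
#' @return list with `curves` (per-node data.frames `time`, `surv`),
#'   `survAtHorizon`, `logrank` (`NULL` for a single node)
#' @export
kmByGroup <- function(stratification, outcome, horizon = 10) {
  checkOutcome(outcome)
  g <- stratification@groups
  stopifnot(length(g) == nrow(outcome))
  k <- length(stratification@nodeSizes)
  curves <- lapply(seq_len(k), function(node) {
    idx <- which(g == node)
    sf <- survival::survfit(
      survival::Surv(outcome$time[idx], outcome$status[idx]) ~ 1)
    data.frame(time = sf$time, surv = sf$surv)
  })
  names(curves) <- paste0("Node", seq_len(k))
  survAtH <- vapply(seq_len(k), function(node) {
    idx <- which(g == node)
    sf <- survival::survfit(
      survival::Surv(outcome$time[idx], outcome$status[idx]) ~ 1)
    s <- summary(sf, times = horizon, extend = TRUE)$surv
    if (length(s)) s else NA_real_
  }, numeric(1))
  names(survAtH) <- names(curves)
  lr <- if (k >= 2) logrankTest(g, outcome) else NULL
  list(curves = curves, survAtHorizon = survAtH, logrank = lr)
}

#' Intersections of best-prognosis groups across signatures
#'
#' For every non-empty combination of signatures, intersects their Node 1
#' (best-prognosis) member sets, estimates the Kaplan-Meier survival
#' probability at the horizon for the shared patients, and flags the
#' full intersection ("All intersecting"), the combination with the
#' maximal survival probability ("Best intersection"), and combinations
#' smaller than a reliability floor.
#'
#' @param bestSets named list: signature name -> character vector of
#'   member sample IDs (the Node 1 sets)
#' @param outcome data.frame(time, status) with sample IDs as rownames
#' @param horizon survival probability report time (default 10 years)
#' @param codes optional named single-letter codes per signature
#'   (defaults to first letters, made unique)
#' @param reliabilityFloor flag combinations with fewer members (default
#'   130)
#' @return data.frame: `code`, `signatures`, `nSignatures`, `n`,
#'   `survProb`, `allIntersecting`, `bestIntersection`, `reliable`
#' @export
intersectBestGroups <- function(bestSets, outcome, horizon = 10,
                                codes = NULL, reliabilityFloor = 130) {
  checkOutcome(outcome)
  stopifnot(length(bestSets) >= 1, !is.null(names(bestSets)))
  ids <- rownames(outcome)
  bad <- setdiff(unlist(bestSets), ids)
  if (length(bad))
    stop("member IDs absent from outcome: ", paste(bad[1:min(3, length(bad))],
                                                   collapse = ", "))
  K <- length(bestSets)
  if (is.null(codes)) {
    codes <- toupper(substr(names(bestSets), 1, 1))
    while (anyDuplicated(codes)) {
      i <- which(duplicated(codes))[1]
      codes[i] <- LETTERS[which(!LETTERS %in% codes)[1]]
    }
    names(codes) <- names(bestSets)
  }
  combos <- lapply(seq_len(2^K - 1), function(m) {
    which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0)
  })
  kmProb <- function(members) {
    if (length(members) == 0) return(NA_real_)
    idx <- match(members, ids)
    sf <- survival::survfit(
      survival::Surv(outcome$time[idx], outcome$status[idx]) ~ 1)
    s <- summary(sf, times = horizon, extend = TRUE)$surv
    if (length(s)) s else NA_real_
  }
  rows <- lapply(combos, function(sel) {
    members <- Reduce(intersect, bestSets[sel])
    data.frame(
      code = paste(codes[names(bestSets)[sel]], collapse = ""),
      signatures = paste(names(bestSets)[sel], collapse = "+"),
      nSignatures = length(sel), n = length(members),
      survProb = kmProb(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$allIntersecting <- out$nSignatures == K
  best <- which.max(ifelse(is.na(out$survProb), -Inf, out$survProb))
  out$bestIntersection <- seq_len(nrow(out)) == best
  out$reliable <- out$n >= reliabilityFloor
  out[order(-out$nSignatures, out$code), ]
}

#' Per-patient agreement profile across signature predictions
#'
#' Summarizes, per patient, the spread of predicted survival
#' probabilities across signatures (min, max, range, sd), plus a cohort
#' summary of the ranges. Patients missing from any prediction map are
#' dropped with a warning.
#'
#' @param predictions named list: signature name -> named numeric vector
#'   of per-patient predicted S(horizon)
#' @return list with `perPatient` (data.frame) and `summary`
#' @export
agreementProfile <- function(predictions) {
  stopifnot(length(predictions) >= 2)
  idSets <- lapply(predictions, names)
  shared <- Reduce(intersect, idSets)
  dropped <- length(unique(unlist(idSets))) - length(shared)
  if (dropped > 0)
    warning(sprintf("dropping %d patient(s) missing from some signature",
                    dropped))
  if (length(shared) == 0) stop("no shared patients across signatures")
  M <- vapply(predictions, function(p) p[shared],
              numeric(length(shared)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1,
                                   dimnames = list(shared, names(predictions)))
  per <- data.frame(
    sample_id = shared,
    min = apply(M, 1, min), max = apply(M, 1, max),
    range = apply(M, 1, max) - apply(M, 1, min),
    sd = apply(M, 1, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  list(perPatient = per,
       summary = c(meanRange = mean(per$range),
                   maxRange = max(per$range),
                   medianSd = stats::median(per$sd)))
}
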