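# Synthetic cohort generator: latent proliferation factor, planted
# prognostic genes, NPI-like clinical score, Weibull proportional-hazards
# survival, right censoring.

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a hormone-receptor-
#' positive breast-cancer expression cohort: a latent per-patient
#' proliferation factor loads on a fraction of the transcriptome (so that
#' random gene signatures carry prognostic signal), a small disjoint set
#' of truly prognostic genes acts directly on the hazard, and an NPI-like
#' clinical score is generated from tumor size / nodal stage / grade that
#' are positively associated with the latent factor without duplicating it.
#' Survival times follow a Weibull-baseline proportional-hazards model;
#' censoring is the minimum of an administrative horizon and exponential
#' dropout.
#'
#' @param nPatients,nGenes cohort dimensions
#' @param prolifFraction fraction of genes loading on the latent factor
#' @param loadingSd standard deviation of the nonzero loadings
#' @param nTrueGenes number of planted directly-prognostic genes (drawn
#'   from the non-loading genes)
#' @param betaTrue log-hazard effects of the planted genes (recycled to
#'   `nTrueGenes`)
#' @param betaProlif log-hazard effect of the latent proliferation factor
#' @param betaClinical log-hazard effect of the (mean-centered) NPI
#' @param baselineShape,baselineScale Weibull baseline hazard parameters
#'   (scale in years)
#' @param censorAdminYears administrative censoring horizon (years; `Inf`
#'   disables it)
#' @param dropoutRate exponential dropout rate per year (0 disables)
#' @param targetEventRatio optional event fraction; when set, event times
#'   are rescaled by a root-found factor so the realized event count is
#'   `round(nPatients * targetEventRatio)`
#' @param seed integer seed
#' @return a validated config list of class `"SyntheticConfig"`
#' @export
syntheticConfig <- function(nPatients = 1000, nGenes = 2000,
                            prolifFraction = 0.5, loadingSd = 1,
                            nTrueGenes = 5, betaTrue = 0.5,
                            betaProlif = 0.6, betaClinical = 0.5,
                            baselineShape = 1.5, baselineScale = 20,
                            censorAdminYears = 15, dropoutRate = 0.03,
                            targetEventRatio = NULL, seed = 1) {
  cfg <- list(nPatients = as.integer(nPatients), nGenes = as.integer(nGenes),
              prolifFraction = prolifFraction, loadingSd = loadingSd,
              nTrueGenes = as.integer(nTrueGenes),
              betaTrue = rep_len(betaTrue, nTrueGenes),
              betaProlif = betaProlif, betaClinical = betaClinical,
              baselineShape = baselineShape, baselineScale = baselineScale,
              censorAdminYears = censorAdminYears, dropoutRate = dropoutRate,
              targetEventRatio = targetEventRatio, seed = as.integer(seed))
  stopifnot(cfg$nPatients > 0, cfg$nGenes > 0,
            cfg$prolifFraction >= 0, cfg$prolifFraction <= 1,
            cfg$nTrueGenes >= 0, cfg$baselineShape > 0,
            cfg$baselineScale > 0, cfg$dropoutRate >= 0)
  if (cfg$nTrueGenes > cfg$nGenes * (1 - cfg$prolifFraction) &&
      cfg$nTrueGenes > 0)
    stop("not enough non-loading genes to plant the true genes")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per patient i a latent proliferation factor P_i ~ N(0,1) is drawn; gene
#' g has expression lambda_g * P_i + eps with eps ~ N(0,1), where
#' lambda_g ~ N(0, loadingSd^2) for the loading fraction of genes and 0
#' otherwise. Clinical ordinals (nodal stage, grade) are generated by
#' thresholding 0.5 * P_i + noise at population quantiles, tumor size is
#' lognormal, and the NPI follows from [computeNPI]. The linear predictor
#' is eta_i = sum(betaTrue * x_true) + betaProlif * P_i +
#' betaClinical * (NPI_i - mean NPI); event times are Weibull with
#' survivor exp(-(t/scale)^shape * exp(eta)) and censoring is
#' min(administrative horizon, exponential dropout).
#'
#' @param config a [syntheticConfig] object
#' @return list with `cohort` (a [SignatureCohort-class]) and `truth`
#'   (list: `trueGeneIds`, `loadingGeneIds`, `latentFactor`,
#'   `linearPredictor`, `survivalFn(t, i)`)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  c2 <- config
  withSeed(c2$seed, {
    n <- c2$nPatients
    p <- c2$nGenes
    geneIds <- sprintf("G%05d", seq_len(p))
    sampleIds <- sprintf("S%05d", seq_len(n))
    P <- stats::rnorm(n)

    nLoad <- round(p * c2$prolifFraction)
    loadIdx <- if (nLoad > 0) seq_len(nLoad) + c2$nTrueGenes else integer(0)
    loadIdx <- loadIdx[loadIdx <= p]
    lambda <- numeric(p)
    lambda[loadIdx] <- stats::rnorm(length(loadIdx), 0, c2$loadingSd)
    expr <- matrix(stats::rnorm(p * n), nrow = p,
                   dimnames = list(geneIds, sampleIds))
    expr <- expr + lambda %o% P

    trueIdx <- seq_len(c2$nTrueGenes)
    etaTrue <- if (c2$nTrueGenes > 0) {
      drop(crossprod(expr[trueIdx, , drop = FALSE], c2$betaTrue))
    } else numeric(n)

    tumorSize <- stats::rlnorm(n, log(2.2), 0.4)
    zStage <- 0.5 * P + sqrt(1 - 0.25) * stats::rnorm(n)
    zGrade <- 0.5 * P + sqrt(1 - 0.25) * stats::rnorm(n)
    nodeStage <- as.integer(cut(zStage, c(-Inf, stats::qnorm(0.55),
                                          stats::qnorm(0.85), Inf)))
    grade <- as.integer(cut(zGrade, c(-Inf, stats::qnorm(0.20),
                                      stats::qnorm(0.65), Inf)))
    npi <- computeNPI(tumorSize, nodeStage, grade)

    eta <- etaTrue + c2$betaProlif * P + c2$betaClinical * (npi - mean(npi))

    U <- stats::runif(n)
    eventTime <- c2$baselineScale * (-log(U) * exp(-eta))^(1 / c2$baselineShape)
    dropout <- if (c2$dropoutRate > 0) {
      stats::rexp(n, c2$dropoutRate)
    } else rep(Inf, n)
    censTime <- pmin(c2$censorAdminYears, dropout)

    if (!is.null(c2$targetEventRatio)) {
      targetEvents <- round(n * c2$targetEventRatio)
      # kth smallest ratio eventTime/censTime gives the exact scale factor
      # putting k events before censoring
      ratio <- sort(eventTime / censTime)
      if (targetEvents < 1 || targetEvents > n)
        stop("targetEventRatio out of range for this cohort size")
      hi <- ratio[targetEvents]
      lo <- if (targetEvents < n) ratio[targetEvents + 1L] else hi * 1.01
      k <- 1 / sqrt(hi * lo)
      if (!is.finite(k) || k <= 0) k <- 1 / hi * 0.999
      eventTime <- eventTime * k
    }

    time <- pmin(eventTime, censTime)
    status <- as.integer(eventTime <= censTime)
    time <- pmax(time, 1e-6)
    if (sum(status) == 0)
      stop("no events generated; increase follow-up or hazard parameters")

    clin <- data.frame(sample_id = sampleIds, time_years = time,
                       status = status, er = "pos", her2 = "neg",
                       chemo = "no",
                       age = round(stats::rnorm(n, 60, 10)),
                       tumor_size_cm = tumorSize, node_stage = nodeStage,
                       grade = grade, npi = npi,
                       stringsAsFactors = FALSE)
    cohort <- makeCohort(expr, clin)
    shape <- c2$baselineShape
    scale <- c2$baselineScale
    truth <- list(
      trueGeneIds = geneIds[trueIdx],
      loadingGeneIds = geneIds[loadIdx],
      latentFactor = stats::setNames(P, sampleIds),
      linearPredictor = stats::setNames(eta, sampleIds),
      survivalFn = function(t, i) exp(-(t / scale)^shape * exp(eta[i]))
    )
    list(cohort = cohort, truth = truth)
  })
}
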