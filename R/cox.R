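# Proportional-hazards fitting and per-patient risk prediction.

#' Fit a Cox proportional-hazards model for a signature design
#'
#' Maximum-partial-likelihood fit with Efron tie handling, Wald 95%
#' intervals and p-values, Breslow baseline cumulative hazard (at the
#' standardized covariate center), and both model and null partial
#' log-likelihoods. On (quasi-)separation the fit is stabilized with a
#' light ridge penalty and a warning is raised.
#'
#' @param design a [SignatureDesign-class]
#' @param outcome data.frame(time, status), e.g. from [survOutcome]
#' @return a [CoxSignatureFit-class]
#' @export
fitCox <- function(design, outcome) {
  checkOutcome(outcome)
  X <- design@values
  if (nrow(X) != nrow(outcome))
    stop("design and outcome disagree on the number of patients")
  if (sum(outcome$status) < 2) stop("need at least 2 events to fit")
  y <- survival::Surv(outcome$time, outcome$status)
  df <- data.frame(X, check.names = FALSE)
  fit <- withCallingHandlers(
    survival::coxph(y ~ ., data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w))) {
        warning("separation detected; refitting with ridge stabilization",
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15)) {
    fit <- survival::coxph(y ~ survival::ridge(X, theta = 1),
                           ties = "efron")
    cf <- stats::coef(fit)
    names(cf) <- colnames(X)
    se <- sqrt(diag(fit$var))
  } else {
    cf <- stats::coef(fit)
    names(cf) <- colnames(X)
    se <- sqrt(diag(fit$var))
  }
  z <- cf / se
  pv <- 2 * stats::pnorm(-abs(z))
  ci <- cbind(lower = exp(cf - 1.96 * se), upper = exp(cf + 1.96 * se))
  rownames(ci) <- names(cf)
  bh <- breslowBaseline(X, cf, outcome)
  new("CoxSignatureFit",
      coefficients = cf, hazardRatios = exp(cf), ci95 = ci,
      pValues = stats::setNames(pv, names(cf)),
      loglikModel = fit$loglik[2], loglikNull = fit$loglik[1],
      n = nrow(X), nEvents = as.integer(sum(outcome$status)),
      baselineCumhaz = bh)
}

# Breslow estimator of the baseline cumulative hazard at covariates 0.
breslowBaseline <- function(X, beta, outcome) {
  lp <- drop(X %*% beta)
  risk <- exp(lp)
  et <- sort(unique(outcome$time[outcome$status == 1]))
  haz <- vapply(et, function(t) {
    d <- sum(outcome$status == 1 & outcome$time == t)
    d / sum(risk[outcome$time >= t])
  }, numeric(1))
  data.frame(time = et, hazard = cumsum(haz))
}

#' Predict per-patient risk from a fitted signature model
#'
#' Computes the linear predictor `x %*% beta`, the relative hazard
#' `exp(lp - mean(lp))` (per-patient hazard ratio relative to the
#' cohort-average profile, geometric-mean centered at 1), and absolute
#' survival curves `S(t | x) = exp(-H0(t) * exp(lp))` over a time grid.
#'
#' @param fit a [CoxSignatureFit-class]
#' @param design a [SignatureDesign-class] standardized with the training
#'   stats (its features must match the fit)
#' @param timeGrid evaluation times in years (default: the baseline
#'   hazard's event times, truncated at 10 years)
#' @return a [RiskPredictions-class]
#' @export
predictRisk <- function(fit, design, timeGrid = NULL) {
  X <- design@values
  if (!setequal(colnames(X), names(fit@coefficients)))
    stop("design features do not match the fit: missing [",
         paste(setdiff(names(fit@coefficients), colnames(X)),
               collapse = ", "),
         "], extra [",
         paste(setdiff(colnames(X), names(fit@coefficients)),
               collapse = ", "), "]")
  X <- X[, names(fit@coefficients), drop = FALSE]
  lp <- drop(X %*% fit@coefficients)
  names(lp) <- rownames(X)
  if (is.null(timeGrid)) {
    timeGrid <- fit@baselineCumhaz$time
    timeGrid <- timeGrid[timeGrid <= 10]
    if (length(timeGrid) == 0) timeGrid <- fit@baselineCumhaz$time
  }
  timeGrid <- sort(unique(c(0, timeGrid)))
  H0 <- stepEval(fit@baselineCumhaz$time, fit@baselineCumhaz$hazard,
                 timeGrid, left0 = 0)
  curves <- exp(-outer(exp(lp), H0))
  dimnames(curves) <- list(rownames(X), NULL)
  new("RiskPredictions",
      linearPredictor = lp,
      relativeHazard = exp(lp - mean(lp)),
      survivalCurves = curves, timeGrid = timeGrid)
}

#' Bivariable Cox model of the NPI and a signature score
#'
#' Fits the two-covariate proportional-hazards model combining the
#' clinical index with a signature's linear predictor, flagging
#' collinearity via the variance inflation factor.
#'
#' @param npi per-patient NPI scores
#' @param signatureScore per-patient signature linear predictor
#' @param outcome data.frame(time, status)
#' @return list with `fit` (a [CoxSignatureFit-class]) and `vif`
#' @export
bivariableFit <- function(npi, signatureScore, outcome) {
  X <- cbind(NPI = as.numeric(npi), score = as.numeric(signatureScore))
  rownames(X) <- rownames(outcome)
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) stop("constant covariate in bivariable model")
  r <- stats::cor(X[, 1], X[, 2])
  v <- if (abs(r) > 1 - 1e-10) Inf else 1 / (1 - r^2)
  if (!is.finite(v) || v > 100)
    warning(sprintf("severe collinearity between NPI and score (VIF = %s)",
                    format(v, digits = 3)))
  Xs <- scale(X)
  design <- new("SignatureDesign", values = Xs[, , drop = FALSE],
                center = stats::setNames(attr(Xs, "scaled:center"),
                                         colnames(X)),
                scale = stats::setNames(attr(Xs, "scaled:scale"),
                                        colnames(X)))
  list(fit = fitCox(design, outcome), vif = c(NPI = v, score = v))
}
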