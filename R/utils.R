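# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from (seed, stage label), kept below 2^31.
childSeed <- function(seed, label) {
  h <- sum(as.integer(charToRaw(as.character(label))) *
           seq_along(charToRaw(as.character(label))))
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483647)
}

# Right-continuous step evaluation of a cumulative function defined by
# (times, values) with value `left0` before the first time.
stepEval <- function(times, values, at, left0 = 0) {
  if (length(times) == 0L) return(rep(left0, length(at)))
  idx <- findInterval(at, times)
  c(left0, values)[idx + 1L]
}

# Kaplan-Meier estimate of the censoring distribution G(t) = P(C > t).
# Returns a list with right-continuous eval G(t) and left-limit G(t-).
censoringKM <- function(time, status) {
  fit <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  tms <- fit$time
  srv <- fit$surv
  list(
    G = function(at) stepEval(tms, srv, at, left0 = 1),
    Gminus = function(at) stepEval(tms, srv, at - 1e-10, left0 = 1)
  )
}

# Pooled Nelson-Aalen cumulative hazard evaluated at each subject's own
# time; E_g = sum over group of these equals the logrank expected count.
nelsonAalenAtOwnTime <- function(time, status) {
  ord <- order(time)
  t_s <- time[ord]
  d_s <- status[ord]
  n <- length(t_s)
  atRisk <- n - seq_len(n) + 1L
  uniq <- !duplicated(t_s)
  # events and at-risk at each unique time
  dt <- tapply(d_s, t_s, sum)
  nt <- tapply(seq_len(n), t_s, function(i) n - min(i) + 1L)
  haz <- as.numeric(dt) / as.numeric(nt)
  cum <- cumsum(haz)
  ut <- as.numeric(names(dt))
  H <- stepEval(ut, cum, time)
  H
}

# Truncate an outcome data.frame(time, status) at a horizon: follow-up
# beyond the horizon is administratively censored there.
truncateOutcome <- function(outcome, horizon) {
  if (is.null(horizon) || !is.finite(horizon)) return(outcome)
  over <- outcome$time > horizon
  outcome$status[over] <- 0
  outcome$time[over] <- horizon
  outcome
}

checkOutcome <- function(outcome) {
  stopifnot(is.data.frame(outcome),
            all(c("time", "status") %in% colnames(outcome)))
  if (any(outcome$time <= 0)) stop("survival times must be > 0")
  if (!all(outcome$status %in% c(0, 1))) stop("status must be 0/1")
  invisible(outcome)
}
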