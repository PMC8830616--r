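test_that("concordance follows the printed pair formula on hand fixtures", {
  # perfectly concordant, uncensored, no ties
  out <- outcomeDf(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(concordanceIndex(c(0.1, 0.2, 0.3, 0.4), out), 1.0)
  # C=2, D=1 fixture: c = 0.5*((2-1)/3 + 1) = 2/3
  out2 <- outcomeDf(c(1, 2, 3), c(1, 1, 0))
  expect_equal(concordanceIndex(c(0.5, 0.1, 0.9), out2), 2 / 3)
  # C=1, D=0, Tx=1 fixture: c = 0.75
  out3 <- outcomeDf(c(1, 2, 3), c(1, 0, 0))
  expect_equal(concordanceIndex(c(1, 1, 2), out3), 0.75)
  # outcome ties are incomparable
  out4 <- outcomeDf(c(1, 1), c(1, 1))
  expect_error(concordanceIndex(c(1, 2), out4), "comparable")
})

test_that("concordance equals exhaustive pair enumeration on random fixtures", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    out <- randomOutcome(n)
    s <- sample(round(rnorm(n), 2))       # rounding forces some ties
    oracle <- concordanceOracle(s, out)
    if (is.na(oracle)) next
    expect_equal(concordanceIndex(s, out), oracle)
  }
  # antisymmetry without score ties: c(s) + c(-s) = 1
  set.seed(32)
  out <- randomOutcome(40)
  s <- rnorm(40)
  expect_equal(concordanceIndex(s, out) + concordanceIndex(-s, out), 1)
  # agreement with the survival package on a tie-free fixture
  fit <- survival::concordance(survival::Surv(out$time, out$status) ~ s)
  expect_equal(concordanceIndex(s, out), unname(fit$concordance))
})

test_that("time-dependent AUC matches separation, toys and Mann-Whitney", {
  # cases all scored below all controls at t -> AUC(t) = 1
  out <- outcomeDf(c(1, 1.5, 5, 6, 7), c(1, 1, 0, 0, 0))
  res <- tdAucCurve(c(0.1, 0.2, 0.8, 0.9, 0.7), out, grid = 2)
  expect_equal(res$curve$auc, 1.0)
  # at t: cases {2}, controls {1, 3} -> AUC = 0.5
  out2 <- outcomeDf(c(1, 4, 5), c(1, 0, 0))
  res2 <- tdAucCurve(c(2, 1, 3), out2, grid = 2)
  expect_equal(res2$curve$auc, 0.5)
  # uncensored: AUC(t) equals the Mann-Whitney statistic of cases vs controls
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    time <- rexp(n, 0.3) + 0.01
    out3 <- outcomeDf(time, rep(1, n))
    s <- rnorm(n)
    tt <- unname(quantile(time, runif(1, 0.2, 0.8)))
    cases <- which(time <= tt)
    ctrls <- which(time > tt)
    if (length(cases) == 0 || length(ctrls) == 0) next
    mw <- mean(outer(s[cases], s[ctrls],
                     function(a, b) (a < b) + 0.5 * (a == b)))
    res3 <- tdAucCurve(s, out3, grid = tt)
    expect_equal(res3$curve$auc, mw)
  }
})

test_that("IAUC comparison is a one-sided paired signed-rank test", {
  grid <- seq(0.5, 10, length.out = 20)
  a <- data.frame(time = grid, auc = runif(20, 0.6, 0.7))
  same <- compareIauc(a, a)
  expect_gte(same, 0.5)
  # constant +0.05 shift at 20 points: exact one-sided p = 1/2^20
  b <- data.frame(time = grid, auc = a$auc - 0.05)
  expect_lt(compareIauc(a, b), 0.001)
  expect_gt(compareIauc(b, a), 0.999)
  # complementary behavior on continuous random series
  set.seed(34)
  for (rep in 1:10) {
    x <- data.frame(time = grid, auc = runif(20))
    y <- data.frame(time = grid, auc = runif(20))
    pxy <- compareIauc(x, y)
    pyx <- compareIauc(y, x)
    expect_gte(pxy + pyx, 1 - 1e-8)
    expect_lte(pxy + pyx, 1.1)
  }
  expect_error(compareIauc(a, data.frame(time = grid + 1, auc = a$auc)),
               "grid")
})

test_that("logrank chi-square equals the hand O/E tally", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  status <- c(1, 1, 0, 1, 1, 0, 1, 1)
  grp <- c("a", "a", "a", "a", "b", "b", "b", "b")
  out <- outcomeDf(time, status)
  # hand tally over event times
  O <- c(a = 0, b = 0); E <- c(a = 0, b = 0)
  for (t in time[status == 1]) {
    atRisk <- time >= t
    d <- sum(status == 1 & time == t)
    O <- O + c(a = sum(status == 1 & time == t & grp == "a"),
               b = sum(status == 1 & time == t & grp == "b"))
    E <- E + d * c(a = sum(atRisk & grp == "a"), b = sum(atRisk & grp == "b")) /
      sum(atRisk)
  }
  hand <- sum((O - E)^2 / E)
  res <- logrankTest(grp, out)
  expect_equal(res$chi2, hand, tolerance = 1e-9)
  expect_equal(res$df, 1)
  expect_equal(res$observed, unname(O))
  expect_equal(res$expected, unname(E), tolerance = 1e-12)
  # matches survdiff's O/E tallies exactly
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  expect_equal(res$observed, unname(sd$obs))
  expect_equal(res$expected, unname(sd$exp), tolerance = 1e-12)
  # label swap leaves the statistic unchanged
  res2 <- logrankTest(ifelse(grp == "a", "b", "a"), out)
  expect_equal(res2$chi2, res$chi2)
  expect_error(logrankTest(rep("a", 8), out), "2 non-empty")
})

test_that("Nagelkerke pseudo R2 matches its closed form and is monotone", {
  expect_equal(nagelkerkeR2(-100, -100, 50), 0)
  expect_equal(nagelkerkeR2(-90, -100, 100), 1 - exp(-0.2))
  r <- vapply(seq(0, 20, by = 2), function(g)
    nagelkerkeR2(-100 + g, -100, 80), numeric(1))
  expect_true(all(diff(r) > 0))
  expect_error(nagelkerkeR2(-101, -100, 50), "below the null")
})

test_that("Brier score matches boundary cases and a hand IPCW oracle", {
  # uncensored, perfect predictions -> 0
  out <- outcomeDf(c(1, 2, 8, 9), c(1, 1, 0, 0))
  expect_equal(brierScore(c(0, 0, 1, 1), out, tStar = 5), 0)
  # uncensored, constant 0.5 -> 0.25
  outU <- outcomeDf(c(1, 2, 8, 9), rep(1, 4))
  expect_equal(brierScore(rep(0.5, 4), outU, tStar = 5), 0.25)
  # uncensored: equals the plain mean squared error
  set.seed(35)
  n <- 30
  outM <- outcomeDf(rexp(n, 0.3) + 0.01, rep(1, n))
  S <- runif(n)
  mse <- mean(ifelse(outM$time <= 4, (0 - S)^2, (1 - S)^2))
  expect_equal(brierScore(S, outM, tStar = 4), mse)
  # censored 6-patient fixture vs a from-first-principles weighted sum
  t6 <- c(1, 2, 3, 4, 5, 6)
  d6 <- c(1, 0, 1, 0, 1, 0)
  S6 <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  out6 <- outcomeDf(t6, d6)
  # censoring KM: drops at censoring times 2, 4, 6
  G <- function(x) {                     # right-continuous
    if (x < 2) 1 else if (x < 4) 1 - 1 / 5 else if (x < 6) (4 / 5) * (2 / 3)
    else 0
  }
  tStar <- 4.5
  hand <- (S6[1]^2 / G(1 - 1e-9) + S6[3]^2 / G(3 - 1e-9) +
             (1 - S6[5])^2 / G(tStar) + (1 - S6[6])^2 / G(tStar)) / 6
  expect_equal(brierScore(S6, out6, tStar), hand, tolerance = 1e-9)
})

test_that("signature skill score matches its definition and is scale-free", {
  expect_equal(signatureSkillScore(0.25, rep(0.25, 10)), 0)
  expect_equal(signatureSkillScore(0.10, rep(0.25, 100)), 0.6)
  expect_equal(signatureSkillScore(0.1, 0.2), 0.5)
  sss <- signatureSkillScore(0.12, c(0.2, 0.25, 0.3))
  expect_equal(signatureSkillScore(3 * 0.12, 3 * c(0.2, 0.25, 0.3)), sss)
  expect_error(signatureSkillScore(0.1, numeric(0)), "empty")
  expect_error(signatureSkillScore(0.1, c(-0.2, 0.1)), "> 0")
})

test_that("calibration reports per-bin KM errors, MAE and Q90", {
  set.seed(36)
  # constant prediction on an uncensored cohort: MAE ~ |p - q|
  n <- 2000
  q <- 0.7
  outC <- outcomeDf(ifelse(runif(n) < 1 - q, runif(n, 0, 4.9),
                           runif(n, 5.1, 20)), rep(1, n))
  p <- 0.55
  calC <- calibrationAssess(rep(p, n) + rnorm(n, 0, 1e-6), outC, tStar = 5)
  expect_lt(abs(calC$mae - abs(p - mean(outC$time > 5))), 0.03)
  # predictions equal to the generating survivor function: small MAE
  S <- runif(n, 0.2, 0.95)
  outS <- outcomeDf(ifelse(runif(n) < S, runif(n, 5.1, 30),
                           runif(n, 0.1, 4.9)), rep(1, n))
  cal <- calibrationAssess(S, outS, tStar = 5, nBins = 10)
  expect_lt(cal$mae, 0.04)
  expect_equal(nrow(cal$curve), 10)
  # quantile ordering of the error summaries
  errs <- abs(cal$curve$observed - cal$curve$predicted)
  expect_gte(cal$q90, median(errs))
  expect_gte(cal$q90, cal$mae - 1e-12)
  expect_equal(cal$range, range(S))
})

test_that("variance inflation factors follow the 1/(1-R2) closed form", {
  set.seed(37)
  n <- 500
  # orthogonal features
  X <- qr.Q(qr(matrix(rnorm(n * 3), ncol = 3)))
  colnames(X) <- c("a", "b", "c")
  v <- vif(X)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-6)
  # exact known correlation via residual orthogonalization: r = 0.8
  z1 <- drop(scale(rnorm(n)))
  e <- residuals(lm(rnorm(n) ~ z1))     # exactly orthogonal to 1 and z1
  e <- e / sd(e)
  z2 <- 0.8 * z1 + 0.6 * e
  v2 <- vif(cbind(x = z1, y = z2))
  expect_equal(unname(v2), rep(1 / (1 - 0.64), 2), tolerance = 1e-6)
  # duplicated column is flagged infinite
  v3 <- vif(cbind(x = z1, y = z1))
  expect_true(all(is.infinite(v3)))
  expect_error(vif(matrix(1:5, ncol = 1)), "2 features")
})

test_that("random reference is seeded and reports full metric sets", {
  cfg <- syntheticConfig(nPatients = 300, nGenes = 100, seed = 12)
  g <- generateCohort(cfg)
  parts <- splitCohort(g$cohort, 0.7, seed = 2)
  r1 <- randomReference(parts$train, parts$test, k = 10, nRandom = 1,
                        seed = 5)
  expect_length(r1$reports, 1)
  expect_s4_class(r1$reports[[1]], "MetricReport")
  r2 <- randomReference(parts$train, parts$test, k = 10, nRandom = 3,
                        seed = 5)
  expect_equal(r1$brier[1], r2$brier[1])   # same seed, same first draw
  expect_length(r2$brier, 3)
})
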