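test_that("constant scores yield a single node", {
  set.seed(51)
  out <- randomOutcome(120, censorFrac = 0.2)
  st <- partitionRiskGroups(rep(1, 120), out, minbucket = 10, B = 99)
  expect_length(st@nodeSizes, 1)
  expect_equal(st@nodeSizes, 120L)
})

test_that("a two-component hazard mixture is split into exactly 2 nodes", {
  set.seed(52)
  n <- 400
  comp <- rep(c(0, 1), each = n / 2)
  haz <- 0.05 * ifelse(comp == 1, 6, 1)
  tt <- rexp(n, haz)
  out <- outcomeDf(pmin(tt, 12), as.integer(tt < 12))
  score <- comp + rnorm(n, 0, 0.05)        # hazard score separates components
  st <- partitionRiskGroups(score, out, minbucket = 20, B = 299, seed = 4)
  expect_length(st@nodeSizes, 2)
  # the threshold separates the mixture components (up to the sampling
  # noise of the maximally selected statistic: >= 98% agreement)
  expect_gte(mean((st@groups - 1L) == comp), 0.98)
  # every node respects minbucket; Node numbering tracks increasing risk
  expect_true(all(st@nodeSizes >= 20))
  expect_lt(mean(st@groups[comp == 0]), mean(st@groups[comp == 1]))
})

test_that("partitions are invariant to monotone transforms of the score", {
  set.seed(53)
  n <- 300
  score <- rnorm(n)
  haz <- 0.08 * exp(score)
  tt <- rexp(n, haz)
  out <- outcomeDf(pmin(tt, 12), as.integer(tt < 12))
  s1 <- partitionRiskGroups(score, out, minbucket = 20, B = 199, seed = 9)
  s2 <- partitionRiskGroups(exp(score), out, minbucket = 20, B = 199,
                            seed = 9)
  expect_identical(s1@groups, s2@groups)
})

test_that("asymptotic and permutation p-values agree on clear fixtures", {
  set.seed(54)
  n <- 300
  comp <- rep(c(0, 1), each = n / 2)
  haz <- 0.05 * ifelse(comp == 1, 5, 1)
  tt <- rexp(n, haz)
  out <- outcomeDf(pmin(tt, 12), as.integer(tt < 12))
  score <- comp + rnorm(n, 0, 0.05)
  sp <- partitionRiskGroups(score, out, minbucket = 30, B = 999, seed = 2)
  sa <- partitionRiskGroups(score, out, minbucket = 30,
                            pMethod = "asymptotic")
  expect_identical(sa@groups, sp@groups)
  expect_lt(abs(sp@splitPValues[1] - sa@splitPValues[1]), 0.02)
})

test_that("KM per group matches closed forms and pools correctly", {
  # uncensored single group: S(t) = (n - k)/n
  out <- outcomeDf(c(1, 2, 3, 11, 12, 13, 14, 15, 16, 17), rep(1, 10))
  st <- new("RiskStratification", thresholds = numeric(0),
            groups = rep(1L, 10), splitPValues = numeric(0),
            nodeSizes = 10L, nodeEvents = 3L)
  km <- kmByGroup(st, out, horizon = 10)
  expect_equal(unname(km$survAtHorizon["Node1"]), 7 / 10)
  expect_null(km$logrank)
  # all patients in one group reproduce the pooled KM
  pooled <- survival::survfit(survival::Surv(out$time, out$status) ~ 1)
  expect_equal(km$curves$Node1$surv, pooled$surv)
  # two groups from the same generator: p roughly uniform
  set.seed(55)
  pv <- replicate(100, {
    o <- randomOutcome(60, censorFrac = 0.3)
    g <- rep(1:2, each = 30)
    st2 <- new("RiskStratification", thresholds = 0.5,
               groups = as.integer(g), splitPValues = 0.01,
               nodeSizes = c(30L, 30L),
               nodeEvents = as.integer(tapply(o$status, g, sum)))
    kmByGroup(st2, o)$logrank$p
  })
  expect_gt(mean(pv > 0.05), 0.85)
  expect_gt(min(pv), 1e-4)
})

test_that("best-group intersections follow set laws and hand KM", {
  # toy: two signatures sharing 3 of 6 patients, 1 event among shared
  out <- outcomeDf(c(2, 12, 12, 3, 12, 12), c(1, 0, 0, 1, 0, 0),
                   ids = paste0("P", 1:6))
  best <- list(SigA = c("P1", "P2", "P3", "P4"),
               SigB = c("P1", "P2", "P3", "P5"))
  rep <- intersectBestGroups(best, out, horizon = 10, reliabilityFloor = 2)
  ab <- rep[rep$code == "SS" | rep$nSignatures == 2, ]
  expect_equal(ab$n, 3)
  expect_equal(ab$survProb, 2 / 3)         # KM: one event among 3 uncensored-at-10
  # K = 1 entries reproduce each signature's own numbers
  a <- rep[rep$signatures == "SigA", ]
  expect_equal(a$n, 4)
  # nested sets: intersection equals the smaller set
  best2 <- list(Inner = c("P1", "P2"), Outer = c("P1", "P2", "P3"))
  rep2 <- intersectBestGroups(best2, out, horizon = 10)
  expect_equal(rep2$n[rep2$nSignatures == 2],
               rep2$n[rep2$signatures == "Inner"])
  # monotone containment across all combinations
  set.seed(56)
  ids <- paste0("P", 1:50)
  outBig <- outcomeDf(rexp(50, 0.1) + 0.1, rbinom(50, 1, 0.5), ids = ids)
  sets <- lapply(1:4, function(i) sample(ids, sample(20:40, 1)))
  names(sets) <- paste0("Sig", 1:4)
  repBig <- intersectBestGroups(sets, outBig, horizon = 5)
  for (i in seq_len(nrow(repBig))) {
    nms <- strsplit(repBig$signatures[i], "+", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(repBig))) {
      nms2 <- strsplit(repBig$signatures[j], "+", fixed = TRUE)[[1]]
      if (all(nms %in% nms2)) expect_lte(repBig$n[j], repBig$n[i])
    }
  }
  expect_equal(sum(repBig$allIntersecting), 1)
  expect_equal(sum(repBig$bestIntersection), 1)
})

test_that("agreement profiles summarize prediction spread per patient", {
  ids <- paste0("P", 1:5)
  p1 <- setNames(c(0.9, 0.8, 0.7, 0.6, 0.5), ids)
  # identical maps: zero spread
  ag <- agreementProfile(list(A = p1, B = p1))
  expect_true(all(ag$perPatient$range == 0))
  # constant shift: all ranges equal the shift
  ag2 <- agreementProfile(list(A = p1, B = p1 - 0.1))
  expect_equal(ag2$perPatient$range, rep(0.1, 5))
  # random maps: brute-force per-patient recomputation
  set.seed(57)
  maps <- lapply(1:4, function(i) setNames(runif(5), ids))
  names(maps) <- paste0("S", 1:4)
  ag3 <- agreementProfile(maps)
  M <- do.call(cbind, maps)
  expect_equal(ag3$perPatient$range,
               unname(apply(M, 1, max) - apply(M, 1, min)))
  expect_equal(ag3$summary[["meanRange"]], mean(ag3$perPatient$range))
  # missing patients are dropped with a warning
  expect_warning(ag4 <- agreementProfile(
    list(A = p1, B = p1[1:3])), "dropping")
  expect_equal(nrow(ag4$perPatient), 3)
})
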