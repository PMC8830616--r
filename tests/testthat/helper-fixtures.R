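# Shared fixture builders: everything is generated in code at test time.

# Tiny hand-made cohort with fully controlled values.
toyCohort <- function(n = 6, nGenes = 4, seed = 42) {
  set.seed(seed)
  genes <- paste0("G", seq_len(nGenes))
  ids <- paste0("S", seq_len(n))
  mat <- matrix(round(rnorm(nGenes * n, 8, 1), 4), nrow = nGenes,
                dimnames = list(genes, ids))
  clin <- data.frame(
    sample_id = ids,
    time_years = round(runif(n, 0.5, 12), 3),
    status = rbinom(n, 1, 0.5),
    er = rep(c("pos", "neg"), length.out = n),
    her2 = rep(c("neg", "neg", "pos"), length.out = n),
    chemo = rep(c("no", "yes"), length.out = n),
    age = sample(40:85, n, replace = TRUE),
    tumor_size_cm = round(runif(n, 0.8, 5), 2),
    node_stage = sample(1:3, n, replace = TRUE),
    grade = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (sum(clin$status) < 2) clin$status[1:2] <- 1
  makeCohort(mat, clin)
}

# Simple outcome data.frame builder.
outcomeDf <- function(time, status, ids = NULL) {
  if (is.null(ids)) ids <- paste0("P", seq_along(time))
  data.frame(time = time, status = status, row.names = ids)
}

# Random censored fixture for property-style loops.
randomOutcome <- function(n, censorFrac = 0.3) {
  time <- round(rexp(n, 0.2) + 0.05, 3)
  status <- as.integer(runif(n) > censorFrac)
  outcomeDf(time, status)
}

# Exhaustive pair-enumeration oracle for the concordance index.
concordanceOracle <- function(scores, outcome) {
  t <- outcome$time; d <- outcome$status; s <- scores
  C <- D <- Tx <- 0
  n <- length(t)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (t[i] == t[j]) next
    short <- if (t[i] < t[j]) i else j
    long <- if (t[i] < t[j]) j else i
    if (d[short] != 1) next
    if (s[short] < s[long]) C <- C + 1
    else if (s[short] > s[long]) D <- D + 1
    else Tx <- Tx + 1
  }
  if (C + D + Tx == 0) return(NA_real_)
  0.5 * ((C - D) / (C + D + Tx) + 1)
}

# Quick design matrix straight from a numeric matrix.
designFromMatrix <- function(X, standardize = TRUE) {
  if (standardize) {
    ctr <- colMeans(X); scl <- apply(X, 2, sd)
  } else {
    ctr <- setNames(rep(0, ncol(X)), colnames(X))
    scl <- setNames(rep(1, ncol(X)), colnames(X))
  }
  vals <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  new("SignatureDesign", values = vals,
      center = setNames(ctr, colnames(X)),
      scale = setNames(scl, colnames(X)))
}
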