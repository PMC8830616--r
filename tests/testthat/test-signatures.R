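test_that("NPI follows the standard size/stage/grade formula with range checks", {
  expect_equal(computeNPI(2.0, 1, 1), 2.4)
  expect_equal(computeNPI(5.0, 3, 3), 7.0)
  expect_error(computeNPI(1.0, 0, 1), "node stage")
  expect_error(computeNPI(-1, 1, 1), "positive")
  expect_error(computeNPI(1, 1, 4), "grade")
})

test_that("built-in signature roster matches the published gene lists", {
  sigs <- builtinSignatures()
  expect_named(sigs, c("Hybrid", "EndoPredictGL", "OncotypeDxGL", "Random",
                       "NPI+Random", "NPI", "OncotypeDxRed"))
  ep <- sigs$EndoPredictGL
  expect_length(ep@features, 15)
  expect_identical(ep@features[1:3], c("ESR1", "ERBB2", "BIRC5"))
  expect_false(ep@includesNPI)
  expect_length(sigs$OncotypeDxGL@features, 21)
  hy <- sigs$Hybrid
  expect_length(hy@features, 14)
  expect_true(hy@includesNPI)
  expect_identical(hy@features[1], "CDC20")
  # NPI+Random is the Random list with CADPS2 swapped for the NPI
  expect_setequal(sigs$`NPI+Random`@features,
                  setdiff(sigs$Random@features, "CADPS2"))
  expect_true(sigs$`NPI+Random`@includesNPI)
  expect_length(sigs$Random@features, 15)
  # NPI-only signature has no genes
  expect_length(sigs$NPI@features, 0)
  expect_true(sigs$NPI@includesNPI)
  # reduced OncotypeDx drops the five housekeeping normalization genes
  expect_setequal(setdiff(sigs$OncotypeDxGL@features,
                          sigs$OncotypeDxRed@features),
                  c("ACTB", "GAPDH", "RPLP0", "GUSB", "TFRC"))
})

test_that("random signature sampling is seeded, uniform and exhaustive", {
  pool <- paste0("G", 1:50)
  s1 <- sampleRandomSignature(pool, 15, seed = 3)
  s2 <- sampleRandomSignature(pool, 15, seed = 3)
  expect_identical(s1@features, s2@features)
  # exhaustion returns the whole pool
  all50 <- sampleRandomSignature(pool, 50, seed = 1)
  expect_setequal(all50@features, pool)
  expect_error(sampleRandomSignature(pool, 51, seed = 1), "pool too small")
  # exclusion honored
  sx <- sampleRandomSignature(pool, 10, seed = 2, exclude = paste0("G", 1:40))
  expect_true(all(sx@features %in% paste0("G", 41:50)))
  # distinct seeds give distinct draws (collision probability ~ 0)
  draws <- vapply(1:100, function(s)
    paste(sort(sampleRandomSignature(pool, 15, seed = s)@features),
          collapse = ","), character(1))
  expect_gt(length(unique(draws)), 95)
})

test_that("k=1 sampling frequencies stay inside exact multinomial bounds", {
  pool <- paste0("G", 1:10)
  draws <- vapply(1:10000, function(s)
    sampleRandomSignature(pool, 1, seed = s)@features, character(1))
  freq <- table(factor(draws, levels = pool))
  # 99.9% two-sided binomial band for p = 1/10, n = 10000
  lo <- qbinom(0.0005, 10000, 0.1)
  hi <- qbinom(0.9995, 10000, 0.1)
  expect_true(all(freq >= lo & freq <= hi))
})

test_that("design matrices are z-scored and reuse training standardization", {
  co <- toyCohort(n = 8, nGenes = 5, seed = 1)
  sig <- geneSignature("s", c("G1", "G3"), includesNPI = TRUE)
  d <- assembleDesignMatrix(co, sig)
  expect_identical(colnames(d@values), c("G1", "G3", "NPI"))
  expect_equal(unname(colMeans(d@values)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(d@values, 2, sd)), rep(1, 3), tolerance = 1e-9)
  # NPI-only signature degenerates to one z-scored column
  dn <- assembleDesignMatrix(co, geneSignature("NPI", includesNPI = TRUE))
  expect_equal(ncol(dn@values), 1)
  expect_equal(unname(dn@values[, 1]),
               unname(scale(npiScores(co))[, 1]), tolerance = 1e-12)
  # test cohort standardized with training stats: verbatim transform
  co2 <- toyCohort(n = 5, nGenes = 5, seed = 2)
  d2 <- assembleDesignMatrix(co2, sig, standardization = d)
  hand <- (exprsMatrix(co2)["G1", 2] - d@center["G1"]) / d@scale["G1"]
  expect_equal(unname(d2@values[2, "G1"]), unname(hand), tolerance = 1e-12)
  # missing gene is a named error
  expect_error(assembleDesignMatrix(co, geneSignature("x", c("G1", "NOPE"))),
               "NOPE")
})

test_that("signature-space size is exact and satisfies the Pascal identity", {
  expect_identical(signatureSpaceSize(5, 2)$digits, "10")
  expect_identical(signatureSpaceSize(7, 1)$digits, "7")
  expect_identical(signatureSpaceSize(4, 0)$digits, "1")
  expect_error(signatureSpaceSize(3, 4), "exceed")
  big <- signatureSpaceSize(24368, 15)
  expect_identical(big$digits,
    "482977571049206897908475308769420513791953749131658736")
  expect_identical(big$scientific, "4.829775710492069e53")
  # Pascal identity over an exhaustive grid, on exact digit strings
  addStrings <- function(a, b) {       # schoolbook decimal addition
    da <- rev(as.integer(strsplit(a, "")[[1]]))
    db <- rev(as.integer(strsplit(b, "")[[1]]))
    L <- max(length(da), length(db))
    da <- c(da, rep(0L, L - length(da)))
    db <- c(db, rep(0L, L - length(db)))
    s <- da + db
    carry <- 0L
    for (i in seq_len(L)) {
      v <- s[i] + carry
      s[i] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0) { s <- c(s, carry %% 10L); carry <- carry %/% 10L }
    paste(rev(s), collapse = "")
  }
  ok <- TRUE
  for (n in 2:100) for (k in 1:(n - 1)) {
    lhs <- signatureSpaceSize(n, k)$digits
    rhs <- addStrings(signatureSpaceSize(n - 1, k - 1)$digits,
                      signatureSpaceSize(n - 1, k)$digits)
    if (!identical(lhs, rhs)) ok <- FALSE
  }
  expect_true(ok)
})
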