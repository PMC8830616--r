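# Signature objects: NPI, built-in gene lists, random sampling, design
# matrices, and signature-space combinatorics.

#' Construct a GeneSignature
#'
#' @param name signature name
#' @param features character vector of unique gene symbols
#' @param includesNPI include the NPI as a pseudo-feature (default FALSE)
#' @return a [GeneSignature-class]
#' @export
geneSignature <- function(name, features = character(),
                          includesNPI = FALSE) {
  new("GeneSignature", name = name, features = as.character(features),
      includesNPI = includesNPI)
}

#' Nottingham Prognostic Index
#'
#' The standard NPI combines tumor size, nodal stage and histological
#' grade: `NPI = 0.2 * size_cm + node_stage + grade`, with nodal stage and
#' grade as ordinals in 1..3. Lower scores carry better prognosis.
#'
#' @param tumorSizeCm tumor size in cm (> 0)
#' @param nodeStage nodal stage, 1..3
#' @param grade histological grade, 1..3
#' @return numeric NPI score(s)
#' @examples
#' computeNPI(2.0, 1, 1) # 2.4
#' @export
computeNPI <- function(tumorSizeCm, nodeStage, grade) {
  if (any(!is.finite(tumorSizeCm)) || any(tumorSizeCm <= 0))
    stop("tumor size must be positive")
  if (!all(nodeStage %in% 1:3)) stop("node stage must be an ordinal in 1..3")
  if (!all(grade %in% 1:3)) stop("grade must be an ordinal in 1..3")
  0.2 * tumorSizeCm + nodeStage + grade
}

#' Built-in benchmark signatures
#'
#' Returns the packaged signature roster: the Hybrid signature (14 genes +
#' NPI selected by screening on the METABRIC training cohort), the gene
#' lists of the EndoPredict (15 genes) and OncotypeDx (21 genes) assays
#' (gene lists only, not their proprietary risk/recurrence scores), a
#' fixed Random 15-gene negative control, NPI+Random (the Random list with
#' CADPS2 replaced by the NPI), the NPI alone, and OncotypeDxRed (the
#' OncotypeDx list minus its five housekeeping normalization genes ACTB,
#' GAPDH, RPLP0, GUSB, TFRC).
#'
#' @return named list of [GeneSignature-class] objects
#' @export
builtinSignatures <- function() {
  path <- system.file("extdata", "builtin_signatures.tsv",
                      package = "hybridsig", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sigs <- lapply(split(tab$feature, tab$signature), function(feats) feats)
  out <- lapply(names(sigs), function(nm) {
    feats <- sigs[[nm]]
    geneSignature(nm, setdiff(feats, "NPI"), includesNPI = "NPI" %in% feats)
  })
  names(out) <- names(sigs)
  housekeeping <- c("ACTB", "GAPDH", "RPLP0", "GUSB", "TFRC")
  out$OncotypeDxRed <- geneSignature(
    "OncotypeDxRed", setdiff(out$OncotypeDxGL@features, housekeeping))
  order <- c("Hybrid", "EndoPredictGL", "OncotypeDxGL", "Random",
             "NPI+Random", "NPI", "OncotypeDxRed")
  out[order]
}

#' Sample a random gene signature
#'
#' Uniform sample without replacement from a gene pool, reproducible for a
#' given seed; named exclusion sets support negative-control rosters that
#' must avoid previously fixed lists.
#'
#' @param pool character vector of candidate gene symbols
#' @param k signature size
#' @param seed integer seed
#' @param exclude optional list/vector of gene symbols to exclude
#' @param name signature name (default derived from the seed)
#' @return a [GeneSignature-class]
#' @export
sampleRandomSignature <- function(pool, k, seed, exclude = NULL,
                                  name = sprintf("Random_seed%d", seed)) {
  avail <- setdiff(pool, unlist(exclude))
  if (length(avail) < k)
    stop(sprintf("pool too small: %d genes available, %d requested",
                 length(avail), k))
  feats <- withSeed(seed, sample(avail, k))
  geneSignature(name, feats)
}

#' Assemble the design matrix of a signature on a cohort
#'
#' Columns are the signature genes' expression rows transposed to samples
#' x features, with an `NPI` column appended when the signature includes
#' it. Every column is z-scored: with `standardization = "fit"` using its
#' own mean/sd (training contract), or with the `center`/`scale` of a
#' previously fitted [SignatureDesign-class] (test contract: the training
#' transform is applied verbatim).
#'
#' @param cohort a [SignatureCohort-class]
#' @param signature a [GeneSignature-class]
#' @param standardization `"fit"` or a [SignatureDesign-class] whose
#'   center/scale should be reused
#' @return a [SignatureDesign-class]
#' @export
assembleDesignMatrix <- function(cohort, signature,
                                 standardization = "fit") {
  feats <- signature@features
  missing <- setdiff(feats, rownames(cohort))
  if (length(missing))
    stop("signature genes absent from cohort: ",
         paste(missing, collapse = ", "))
  mat <- t(exprsMatrix(cohort)[feats, , drop = FALSE])
  if (signature@includesNPI)
    mat <- cbind(mat, NPI = npiScores(cohort))
  if (ncol(mat) == 0L) stop("signature has no features")
  if (identical(standardization, "fit")) {
    center <- colMeans(mat)
    scale <- apply(mat, 2, stats::sd)
    zero <- scale < 1e-12
    if (any(zero))
      stop("zero-variance column(s): ",
           paste(colnames(mat)[zero], collapse = ", "))
  } else if (is(standardization, "SignatureDesign")) {
    if (!identical(colnames(mat), names(standardization@center)))
      stop("reference standardization features do not match the signature")
    center <- standardization@center
    scale <- standardization@scale
  } else stop("standardization must be \"fit\" or a SignatureDesign")
  vals <- sweep(sweep(mat, 2, center), 2, scale, "/")
  new("SignatureDesign", values = vals, center = center, scale = scale)
}

# ---- exact big-integer binomial -------------------------------------------

# Big naturals as little-endian base-1e7 digit vectors.
bigFromInt <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0)
  d <- integer(0)
  while (x > 0) { d <- c(d, x %% 1e7); x <- x %/% 1e7 }
  d
}

bigMulSmall <- function(a, m) {
  carry <- 0
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    v <- a[i] * m + carry
    out[i] <- v %% 1e7
    carry <- v %/% 1e7
  }
  while (carry > 0) { out <- c(out, carry %% 1e7); carry <- carry %/% 1e7 }
  out
}

bigDivSmall <- function(a, d) {
  out <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    v <- rem * 1e7 + a[i]
    out[i] <- v %/% d
    rem <- v %% d
  }
  if (rem != 0) stop("non-exact big-integer division")
  while (length(out) > 1 && out[length(out)] == 0)
    out <- out[-length(out)]
  out
}

bigToString <- function(a) {
  paste0(c(as.character(a[length(a)]),
           sprintf("%07d", rev(a[-length(a)]))), collapse = "")
}

#' Exact size of the k-gene signature space
#'
#' The number of distinct k-gene signatures drawable from a transcriptome
#' of n genes is the binomial coefficient C(n, k), computed exactly in
#' arbitrary precision (for the study-scale n = 24368, k = 15 the count
#' has 54 digits, far beyond double precision).
#'
#' @param nGenes pool size n
#' @param k signature size
#' @return list with `digits` (exact decimal string), `scientific`
#'   (16-significant-digit scientific notation) and `log10` (numeric)
#' @examples
#' signatureSpaceSize(5, 2)$digits # "10"
#' @export
signatureSpaceSize <- function(nGenes, k) {
  stopifnot(nGenes >= 0, k >= 0)
  if (k > nGenes) stop("k must not exceed the pool size")
  acc <- bigFromInt(1)
  if (k > 0) for (i in seq_len(k)) {
    acc <- bigMulSmall(acc, nGenes - k + i)
    acc <- bigDivSmall(acc, i)
  }
  s <- bigToString(acc)
  nd <- nchar(s)
  mant <- if (nd > 1) {
    signif(as.numeric(paste0(substr(s, 1, 1), ".", substr(s, 2, nd))), 16)
  } else as.numeric(s)
  list(digits = s,
       scientific = sprintf("%.16ge%d", mant, nd - 1L),
       log10 = (nd - 1L) + log10(mant))
}
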