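## Small deterministic fixtures shared across test files.

tinyConfig <- function(...) {
  args <- modifyList(
    list(nSamples = 60, nGenes = 150, nVariants = 300,
         missingFraction = 0.2, seed = 11),
    list(...))
  do.call(simConfig, args)
}

tinyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simCohort(tinyConfig())
    cache
  }
})

## cohort preprocessed to the resid assay
tinyExpr <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- tinyCohort()
      cache <<- residualize(normalizeLogCpm(filterGenes(co@expression)),
                            covariatePCs(co@covariates@raw))
    }
    cache
  }
})

## an ExpressionMatrix built directly from a matrix, for closed-form tests
exprFromMatrix <- function(m, chrom = "1", tss = NULL, strand = NULL) {
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(n))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  new("ExpressionMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(
      chrom = rep_len(chrom, n),
      tss = if (is.null(tss)) seq_len(n) * 1e5 else tss,
      strand = if (is.null(strand)) rep_len("+", n) else strand,
      row.names = rownames(m))))
}

## attach a resid assay directly (for tests that bypass normalization)
withResid <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  e <- exprFromMatrix(matrix(0L, nrow(m), ncol(m),
                             dimnames = dimnames(m)))
  SummarizedExperiment::assay(e, "logcpm") <- m
  SummarizedExperiment::assay(e, "resid") <- m
  e
}

genotypesFromMatrix <- function(d, chrom = "1", pos = NULL) {
  if (is.null(rownames(d))) rownames(d) <- sprintf("v%03d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("s%03d", seq_len(ncol(d)))
  new("GenotypeMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = d),
    rowData = S4Vectors::DataFrame(
      chrom = rep_len(chrom, nrow(d)),
      pos = if (is.null(pos)) seq_len(nrow(d)) * 1e4 else pos,
      row.names = rownames(d))))
}
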