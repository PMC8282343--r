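## Accessors and show() methods; slots are never reached into directly
## by user code.

#' @describeIn GenotypeMatrix-class variants x samples dosage matrix.
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) assay(x, "dosage"))

#' @describeIn GenotypeMatrix-class variant metadata (id, chrom, pos) as
#'   a data.frame.
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) {
  df <- as.data.frame(rowData(x))
  df$id <- rownames(x)
  df[, c("id", setdiff(names(df), "id"))]
})

#' @describeIn ExpressionMatrix-class gene annotation (id, chrom, tss,
#'   strand) as a data.frame.
#' @export
setMethod("geneInfo", "ExpressionMatrix", function(x) {
  df <- as.data.frame(rowData(x))
  df$gene_id <- rownames(x)
  df[, c("gene_id", setdiff(names(df), "gene_id"))]
})

#' @importFrom BiocGenerics counts
#' @describeIn ExpressionMatrix-class raw count matrix.
#' @param object an \code{ExpressionMatrix}.
#' @export
setMethod("counts", "ExpressionMatrix", function(object) {
  assay(object, "counts")
})

#' @describeIn ExpressionMatrix-class log2-CPM matrix (after
#'   \code{\link{normalizeLogCpm}}).
#' @export
setMethod("logCPM", "ExpressionMatrix", function(x) {
  if (!"logcpm" %in% names(assays(x)))
    stop("no 'logcpm' assay; run normalizeLogCpm() first")
  assay(x, "logcpm")
})

#' @describeIn ExpressionMatrix-class residualized expression (after
#'   \code{\link{residualize}}).
#' @export
setMethod("residMatrix", "ExpressionMatrix", function(x) {
  if (!"resid" %in% names(assays(x)))
    stop("no 'resid' assay; run residualize() first")
  assay(x, "resid")
})

#' @describeIn PhenotypeTable-class samples x variables data.frame.
#' @export
setMethod("phenoValues", "PhenotypeTable", function(x) x@data)

#' @describeIn PhenotypeTable-class named character vector of category
#'   labels.
#' @export
setMethod("phenoCategories", "PhenotypeTable", function(x) x@categories)

#' @describeIn CovariateSet-class principal-component scores.
#' @export
setMethod("covariatePCScores", "CovariateSet", function(x) x@pcs)

#' @describeIn CovariateSet-class per-PC fraction of variance explained.
#' @export
setMethod("varianceExplained", "CovariateSet", function(x)
  x@varianceExplained)

#' @describeIn SignatureMatrix-class samples x variables matrix of
#'   imputed values.
#' @export
setMethod("signatureValues", "SignatureMatrix", function(x) x@values)

#' @describeIn SignatureMatrix-class named logical selection flags.
#' @export
setMethod("selectedSignatures", "SignatureMatrix", function(x) x@selected)

#' @describeIn SignatureMatrix-class list of source models.
#' @export
setMethod("signatureModels", "SignatureMatrix", function(x) x@models)

#' @describeIn SignatureModel-class named nonzero gene coefficients.
#' @export
setMethod("signatureWeights", "SignatureModel", function(x) x@weights)

#' @describeIn SignatureModel-class cross-validated variance explained.
#' @export
setMethod("cvR2", "SignatureModel", function(x) x@r2)

#' @describeIn TruthSet-class samples x variables matrix of latent
#'   (noise-free) trait values.
#' @export
setMethod("latentTraits", "TruthSet", function(x) x@latentTraits)

#' @describeIn NullStore-class pooled null p-values.
#' @export
setMethod("nullValues", "NullStore", function(x) x@nullP)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSamples, "samples,", object@nGenes, "genes,",
      object@nVariants, "variants\n")
  cat("  phenotype blocks:",
      paste0(names(object@categoryBlocks), "=", object@categoryBlocks,
             collapse = ", "), "\n")
  cat("  MAF in [", object@mafRange[1], ",", object@mafRange[2],
      "], NB dispersion ", object@nbDispersion,
      ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel for '", object@variable, "': ",
      length(object@weights), " genes, alpha=", object@alpha,
      ", lambda=", signif(object@lambda, 4),
      ", cv r2=", signif(object@r2, 4),
      " (n=", object@nTrain, ")\n", sep = "")
})

setMethod("show", "SignatureMatrix", function(object) {
  cat("SignatureMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "signatures;",
      sum(object@selected), "selected at r2 >=",
      object@r2Threshold, "\n")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@latentTraits), "samples,",
      length(object@betaG), "genes,",
      ncol(object@latentTraits), "latent variables\n")
  cat("  nonzero effects: betaG", sum(object@betaG != 0),
      "| betaE", sum(object@betaE != 0),
      "| betaGxe", sum(object@betaGxe != 0), "\n")
})

setMethod("show", "SimCohort", function(object) {
  cat("SimCohort\n")
  show(object@config)
})

setMethod("show", "NullStore", function(object) {
  cat("NullStore for '", object@signature, "': ", object@nNull,
      " pooled permutation p-values (seed ", object@seed, ")\n", sep = "")
})

setMethod("show", "CovariateSet", function(object) {
  cat("CovariateSet:", nrow(object@raw), "samples x", ncol(object@raw),
      "covariates")
  if (ncol(object@pcs))
    cat(";", ncol(object@pcs), "PCs explaining",
        signif(100 * sum(object@varianceExplained), 4), "% of variance")
  cat("\n")
})

setMethod("show", "PhenotypeTable", function(object) {
  cat("PhenotypeTable:", nrow(object@data), "samples x",
      ncol(object@data), "variables in",
      length(unique(object@categories)), "categories\n")
})
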