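## S4 containers. Matrix-like data ride on SummarizedExperiment so the
## usual Bioconductor subsetting/accessor idioms apply; small model
## objects are plain slots.

#' Configuration of a synthetic cohort
#'
#' Describes one simulated study: cohort size, marker panel, phenotype
#' block structure, per-gene effect sizes and nuisance structure. All
#' stochastic generators (\code{\link{simGenotypes}},
#' \code{\link{simTruth}}, \code{\link{simPhenotypes}},
#' \code{\link{simExpression}}) are driven by \code{seed} plus fixed
#' per-stage offsets, so identical configurations give byte-identical
#' cohorts.
#'
#' @slot nSamples,nGenes,nVariants cohort dimensions.
#' @slot mafRange allele-frequency range, drawn uniformly per variant;
#'   must lie in (0, 0.5].
#' @slot categoryBlocks named integer vector mapping phenotype category
#'   to its number of variables; variables within a block share a common
#'   latent factor.
#' @slot effectSizes \code{nGenes x 3} matrix with columns
#'   \code{betaG}, \code{betaE}, \code{betaGxe}: genetic, environmental
#'   and interaction effects on the natural-log expression mean.
#' @slot nbDispersion negative-binomial dispersion, with
#'   \code{var = mu + dispersion * mu^2}.
#' @slot libsizeRange library sizes are log-uniform in this range.
#' @slot confounderCount number of Gaussian technical confounder axes.
#' @slot noiseSdPhenotype measurement-noise SD added to unit-variance
#'   latent traits (1 gives a true signal fraction of 0.5).
#' @slot missingFraction fraction of samples set missing per phenotype
#'   variable; must be < 1.
#' @slot blockCor within-block correlation of latent traits.
#' @slot seed master seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nSamples = "integer", nGenes = "integer", nVariants = "integer",
    mafRange = "numeric", categoryBlocks = "integer",
    effectSizes = "matrix", nbDispersion = "numeric",
    libsizeRange = "numeric", confounderCount = "integer",
    noiseSdPhenotype = "numeric", missingFraction = "numeric",
    blockCor = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSamples < 1L || object@nGenes < 1L || object@nVariants < 1L)
    msg <- c(msg, "nSamples, nGenes and nVariants must all be >= 1")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must be two nondecreasing values in (0, 0.5]")
  if (any(object@categoryBlocks < 1L) || is.null(names(object@categoryBlocks)))
    msg <- c(msg, "categoryBlocks must be a named vector of counts >= 1")
  if (!identical(dim(object@effectSizes),
                 c(object@nGenes, 3L)) &&
      !identical(dim(object@effectSizes), as.integer(c(object@nGenes, 3))))
    msg <- c(msg, "effectSizes must be an nGenes x 3 matrix")
  if (object@nbDispersion <= 0)
    msg <- c(msg, "nbDispersion must be > 0")
  if (length(object@libsizeRange) != 2L || any(object@libsizeRange <= 0) ||
      diff(object@libsizeRange) < 0)
    msg <- c(msg, "libsizeRange must be two nondecreasing positive values")
  if (object@confounderCount < 0L)
    msg <- c(msg, "confounderCount must be >= 0")
  if (object@noiseSdPhenotype < 0)
    msg <- c(msg, "noiseSdPhenotype must be >= 0")
  if (object@missingFraction < 0 || object@missingFraction >= 1)
    msg <- c(msg, "missingFraction must be in [0, 1)")
  if (object@blockCor < 0 || object@blockCor > 1)
    msg <- c(msg, "blockCor must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic cohort
#'
#' Carries the noise-free quantities from which a synthetic cohort was
#' generated, used by parameter-recovery tests: the latent (noise-free)
#' value of every phenotype variable, per-gene effect sizes and their
#' assigned cis variant / environmental variable, confounder and
#' cell-composition loadings, and the baseline expression level.
#'
#' @slot latentTraits samples x variables matrix of true trait values.
#' @slot betaG,betaE,betaGxe per-gene true effects on the log mean.
#' @slot assignedVariant,assignedVariable per-gene id of the cis variant
#'   carrying \code{betaG}/\code{betaGxe} and of the variable carrying
#'   \code{betaE}/\code{betaGxe} (\code{NA} when the effect is zero).
#' @slot confounderLoadings genes x confounders loading matrix.
#' @slot confounders samples x confounders matrix of technical axes.
#' @slot cellLoadings genes x 4 loadings on cell-composition axes.
#' @slot cellProps samples x 4 latent blood cell proportions (rows sum
#'   to 1).
#' @slot baseLogMean per-gene baseline, natural log of CPM.
#' @exportClass TruthSet
setClass("TruthSet",
  representation(
    latentTraits = "matrix", betaG = "numeric", betaE = "numeric",
    betaGxe = "numeric", assignedVariant = "character",
    assignedVariable = "character", confounderLoadings = "matrix",
    confounders = "matrix", cellLoadings = "matrix", cellProps = "matrix",
    baseLogMean = "numeric"))

setValidity("TruthSet", function(object) {
  msg <- character()
  nG <- length(object@betaG)
  if (length(object@betaE) != nG || length(object@betaGxe) != nG ||
      length(object@assignedVariant) != nG ||
      length(object@assignedVariable) != nG ||
      length(object@baseLogMean) != nG)
    msg <- c(msg, "per-gene slots must all have the same length")
  bad <- object@betaGxe != 0 & is.na(object@assignedVariant)
  if (any(bad))
    msg <- c(msg, sprintf(
      "%d genes have nonzero betaGxe but no assigned cis variant", sum(bad)))
  if (nrow(object@confounderLoadings) &&
      nrow(object@confounderLoadings) != nG)
    msg <- c(msg, "confounderLoadings rows must match genes")
  if (nrow(object@confounders) && nrow(object@cellProps) &&
      nrow(object@confounders) != nrow(object@cellProps))
    msg <- c(msg, "confounders and cellProps must cover the same samples")
  if (length(msg)) msg else TRUE
})

#' Per-sample genotype dosages with variant metadata
#'
#' A \linkS4class{SummarizedExperiment} whose \code{"dosage"} assay holds
#' alternate-allele dosages in [0, 2] (variants x samples) and whose
#' \code{rowData} carries at least \code{chrom} and \code{pos}.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    return("a 'dosage' assay is required")
  d <- assay(object, "dosage")
  if (any(d < 0 | d > 2, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (!all(c("chrom", "pos") %in% names(rowData(object))))
    msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
  if (length(msg)) msg else TRUE
})

#' Expression counts with normalized and residualized views
#'
#' A \linkS4class{SummarizedExperiment} over genes x samples. The
#' \code{"counts"} assay holds raw nonnegative integer counts; the
#' optional \code{"logcpm"} and \code{"resid"} assays are added by
#' \code{\link{normalizeLogCpm}} and \code{\link{residualize}}.
#' \code{rowData} carries the gene annotation (\code{chrom}, \code{tss},
#' \code{strand}).
#'
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    return("a 'counts' assay is required")
  cts <- assay(object, "counts")
  if (any(cts < 0, na.rm = TRUE) ||
      any(abs(cts - round(cts)) > 1e-8, na.rm = TRUE))
    msg <- c(msg, "counts must be nonnegative integers")
  for (a in intersect(c("logcpm", "resid"), names(assays(object))))
    if (!identical(dim(assay(object, a)), dim(cts)))
      msg <- c(msg, sprintf("assay '%s' must match the counts dimensions", a))
  if (!all(c("chrom", "tss", "strand") %in% names(rowData(object))))
    msg <- c(msg, "rowData must contain 'chrom', 'tss' and 'strand'")
  if (length(msg)) msg else TRUE
})

#' Measured phenotype variables with category labels
#'
#' Samples x variables table of measured values (missingness allowed as
#' \code{NA}) plus a category label per variable (e.g. socioeconomic
#' status, emotionality, blood composition).
#'
#' @slot data data.frame, samples in rows, variables in columns.
#' @slot categories named character vector, one label per variable.
#' @exportClass PhenotypeTable
setClass("PhenotypeTable",
  representation(data = "data.frame", categories = "character"))

setValidity("PhenotypeTable", function(object) {
  msg <- character()
  if (!identical(names(object@categories), colnames(object@data)))
    msg <- c(msg, "categories must be named by the phenotype columns")
  if (length(msg)) msg else TRUE
})

#' Technical/biological covariates and their principal components
#'
#' @slot raw samples x covariates data.frame (numeric or categorical).
#' @slot pcs samples x k orthogonal principal-component scores.
#' @slot varianceExplained per-PC fraction of total covariate variance,
#'   nonincreasing and summing to at most 1.
#' @exportClass CovariateSet
setClass("CovariateSet",
  representation(raw = "data.frame", pcs = "matrix",
                 varianceExplained = "numeric"))

setValidity("CovariateSet", function(object) {
  msg <- character()
  if (ncol(object@pcs)) {
    if (ncol(object@pcs) != length(object@varianceExplained))
      msg <- c(msg, "one varianceExplained entry per PC is required")
    if (length(object@varianceExplained) > 1L &&
        any(diff(object@varianceExplained) > 1e-8))
      msg <- c(msg, "varianceExplained must be nonincreasing")
    if (sum(object@varianceExplained) > 1 + 1e-8)
      msg <- c(msg, "varianceExplained must sum to at most 1")
  }
  if (length(msg)) msg else TRUE
})

#' A fitted transcriptional-signature model
#'
#' Sparse elastic-net model predicting one phenotype variable from
#' residualized expression, evaluated by cross-validation. \code{r2} is
#' the cross-validated fraction of variance explained,
#' \code{1 - cvMse / var(y)}; it may be negative.
#'
#' @slot variable phenotype variable name.
#' @slot weights named nonzero gene coefficients (original scale).
#' @slot intercept model intercept.
#' @slot alpha elastic-net mixing parameter in [0, 1].
#' @slot lambda selected penalty.
#' @slot cvMse,cvMseSd cross-validated MSE at \code{lambda} and its SE.
#' @slot r2 cross-validated variance explained.
#' @slot nTrain number of non-missing training samples.
#' @slot geneSubset genes the model was restricted to (empty when
#'   unrestricted).
#' @exportClass SignatureModel
setClass("SignatureModel",
  representation(
    variable = "character", weights = "numeric", intercept = "numeric",
    alpha = "numeric", lambda = "numeric", cvMse = "numeric",
    cvMseSd = "numeric", r2 = "numeric", nTrain = "integer",
    geneSubset = "character"))

setValidity("SignatureModel", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be in [0, 1]")
  if (length(object@weights) && is.null(names(object@weights)))
    msg <- c(msg, "weights must be named by gene")
  if (length(object@geneSubset) && length(object@weights) &&
      !all(names(object@weights) %in% object@geneSubset))
    msg <- c(msg, "weights must be restricted to geneSubset when set")
  if (length(msg)) msg else TRUE
})

#' Imputed (denoised) signature values for a cohort
#'
#' Per-sample predicted values for every modelled variable, including
#' samples whose variable was directly measured (denoising), plus the
#' selection flag derived from the cross-validated r2 threshold.
#'
#' @slot values samples x variables matrix of imputed values.
#' @slot selected named logical, \code{TRUE} where the source model
#'   passes the r2 threshold.
#' @slot models the source \linkS4class{SignatureModel} objects.
#' @slot r2Threshold threshold used to derive \code{selected}.
#' @exportClass SignatureMatrix
setClass("SignatureMatrix",
  representation(values = "matrix", selected = "logical", models = "list",
                 r2Threshold = "numeric"))

setValidity("SignatureMatrix", function(object) {
  msg <- character()
  if (!identical(names(object@selected), colnames(object@values)))
    msg <- c(msg, "selected must be named by the signature columns")
  if (length(object@models) != ncol(object@values))
    msg <- c(msg, "one source model per signature column is required")
  if (length(msg)) msg else TRUE
})

#' A simulated cohort bundle
#'
#' Genotypes, raw expression, measured phenotypes, technical covariates
#' and the generating \linkS4class{TruthSet} for one synthetic cohort.
#'
#' @slot genotypes a \linkS4class{GenotypeMatrix}.
#' @slot expression an \linkS4class{ExpressionMatrix} (raw counts).
#' @slot phenotypes a \linkS4class{PhenotypeTable}.
#' @slot covariates a \linkS4class{CovariateSet} (raw only).
#' @slot truth the generating \linkS4class{TruthSet}.
#' @slot config the \linkS4class{SimConfig} used.
#' @exportClass SimCohort
setClass("SimCohort",
  representation(genotypes = "GenotypeMatrix",
                 expression = "ExpressionMatrix",
                 phenotypes = "PhenotypeTable",
                 covariates = "CovariateSet",
                 truth = "TruthSet",
                 config = "SimConfig"))

#' Configuration of a cis-eQTL scan
#'
#' @slot windowBp cis window around the (strand-aware) TSS, inclusive.
#' @slot mafMin variants require cohort MAF strictly above this.
#' @slot permMin,permMax adaptive permutation bounds.
#' @slot adaptiveStopHits stop permuting once this many permutation
#'   minima beat the observed minimum.
#' @slot fdrLevel gene-level FDR for eGene calls.
#' @slot nExpressionPCs expression PCs added to the residualization.
#' @slot seed seed for the gene-indexed permutation streams.
#' @exportClass CisScanConfig
setClass("CisScanConfig",
  representation(windowBp = "numeric", mafMin = "numeric",
                 permMin = "integer", permMax = "integer",
                 adaptiveStopHits = "integer", fdrLevel = "numeric",
                 nExpressionPCs = "integer", seed = "integer"))

setValidity("CisScanConfig", function(object) {
  msg <- character()
  if (object@permMin > object@permMax)
    msg <- c(msg, "permMin must be <= permMax")
  if (object@mafMin <= 0 || object@mafMin >= 0.5)
    msg <- c(msg, "mafMin must be in (0, 0.5)")
  if (object@fdrLevel <= 0 || object@fdrLevel >= 1)
    msg <- c(msg, "fdrLevel must be in (0, 1)")
  if (object@nExpressionPCs < 0L)
    msg <- c(msg, "nExpressionPCs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Pooled permutation null for interaction p-values
#'
#' Interaction-term p-values obtained by refitting the GxE model on
#' dosage-permuted data, pooled across all lead gene-variant pairs of
#' one signature. Used to convert observed interaction p-values into
#' empirical (permutation-corrected) p-values.
#'
#' @slot signature signature the null belongs to.
#' @slot nullP pooled permutation p-values.
#' @slot nNull number of stored values.
#' @slot seed seed the null was built with.
#' @exportClass NullStore
setClass("NullStore",
  representation(signature = "character", nullP = "numeric",
                 nNull = "integer", seed = "integer"))

setValidity("NullStore", function(object) {
  msg <- character()
  if (length(object@nullP) != object@nNull)
    msg <- c(msg, "nNull must equal the number of stored values")
  if (any(object@nullP < 0 | object@nullP > 1))
    msg <- c(msg, "null p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
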