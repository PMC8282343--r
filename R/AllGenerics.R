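#' @rdname GenotypeMatrix-class
#' @param x a sigQTL object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname ExpressionMatrix-class
#' @param x a sigQTL object.
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("logCPM", function(x) standardGeneric("logCPM"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("residMatrix", function(x) standardGeneric("residMatrix"))

#' @rdname PhenotypeTable-class
#' @param x a sigQTL object.
#' @export
setGeneric("phenoValues", function(x) standardGeneric("phenoValues"))

#' @rdname PhenotypeTable-class
#' @export
setGeneric("phenoCategories", function(x) standardGeneric("phenoCategories"))

#' @rdname CovariateSet-class
#' @param x a sigQTL object.
#' @export
setGeneric("covariatePCScores", function(x) standardGeneric("covariatePCScores"))

#' @rdname CovariateSet-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname SignatureMatrix-class
#' @param x a sigQTL object.
#' @export
setGeneric("signatureValues", function(x) standardGeneric("signatureValues"))

#' @rdname SignatureMatrix-class
#' @export
setGeneric("selectedSignatures", function(x) standardGeneric("selectedSignatures"))

#' @rdname SignatureMatrix-class
#' @export
setGeneric("signatureModels", function(x) standardGeneric("signatureModels"))

#' @rdname SignatureModel-class
#' @param x a sigQTL object.
#' @export
setGeneric("signatureWeights", function(x) standardGeneric("signatureWeights"))

#' @rdname SignatureModel-class
#' @export
setGeneric("cvR2", function(x) standardGeneric("cvR2"))

#' @rdname TruthSet-class
#' @param x a sigQTL object.
#' @export
setGeneric("latentTraits", function(x) standardGeneric("latentTraits"))

#' @rdname NullStore-class
#' @param x a sigQTL object.
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))
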