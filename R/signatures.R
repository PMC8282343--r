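## Transcriptional signatures: sparse elastic-net models
##   phenotype = intercept + sum_n beta_n * E(gene_n)
## fitted on residualized expression, cross-validated, then used to
## impute (denoise) the variable for every sample in the cohort.

## 100 log-spaced penalties from the data-derived lambda_max down to
## lambda_max * 1e-3, on glmnet's standardized scale.
.lambdaGrid <- function(x, y, alpha, nLambda = 100,
                        lambdaMinRatio = 1e-3) {
  xs <- scale(x)
  xs[is.na(xs)] <- 0 # constant genes contribute nothing to lambda_max
  lmax <- max(abs(crossprod(xs, y - mean(y)))) /
    (length(y) * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nLambda))
}

#' Fit one transcriptional-signature model
#'
#' Elastic-net (Gaussian) regression of a phenotype on residualized
#' expression over a descending penalty grid, evaluated by
#' cross-validation on the non-missing samples and refit on all of them
#' at the selected penalty. The mixing parameter defaults to a relaxed
#' \code{alpha = 0.1} so groups of co-regulated genes enter the model
#' together rather than one representative per group.
#'
#' The cross-validated variance explained is
#' \code{r2 = 1 - cvMse / var(y)} (sample variance, n-1 denominator) and
#' may be negative. Penalty selection defaults to the one-standard-error
#' rule (\code{lambdaRule = "1se"}): the largest penalty whose CV error
#' is within one standard error of the minimum. Selecting the exact
#' minimum of the noisy CV curve is available (\code{"min"}) but
#' overstates r2 under the null, because the minimum of ~100 correlated
#' noisy MSE estimates is biased downward.
#'
#' @param y phenotype vector, named by sample, \code{NA} = unmeasured.
#' @param expr an \linkS4class{ExpressionMatrix} with a \code{resid}
#'   assay covering the cohort.
#' @param alpha elastic-net mixing parameter (default 0.1).
#' @param geneSubset optional gene ids to restrict the model to (e.g. a
#'   published signature panel).
#' @param lambdaRule \code{"1se"} (default) or \code{"min"}.
#' @param folds \code{"loo"} for leave-one-out (default) or an integer
#'   k for deterministic k-fold cross-validation.
#' @param nLambda,lambdaMinRatio penalty-grid shape.
#' @param minTrain minimum number of non-missing samples (default 20).
#' @return a \linkS4class{SignatureModel}.
#' @examples
#' co <- simCohort(simConfig(nSamples = 60, nGenes = 150, nVariants = 300,
#'                           missingFraction = 0))
#' expr <- residualize(normalizeLogCpm(filterGenes(co@expression)),
#'                     covariatePCs(co@covariates))
#' y <- phenoValues(co@phenotypes)[, "ses_1"]
#' names(y) <- rownames(phenoValues(co@phenotypes))
#' fit <- fitSignature(y, expr, folds = 5)
#' fit
#' @export
fitSignature <- function(y, expr, alpha = 0.1, geneSubset = NULL,
                         lambdaRule = c("1se", "min"), folds = "loo",
                         nLambda = 100, lambdaMinRatio = 1e-3,
                         minTrain = 20) {
  lambdaRule <- match.arg(lambdaRule)
  r <- residMatrix(expr)
  if (!is.null(geneSubset)) {
    found <- intersect(geneSubset, rownames(r))
    if (!length(found))
      stop("none of the geneSubset genes are present in the expression")
    r <- r[found, , drop = FALSE]
  }
  if (!is.null(names(y))) {
    if (!all(names(y) %in% colnames(r)))
      stop("y contains samples absent from the expression matrix")
    r <- r[, names(y), drop = FALSE]
  } else if (length(y) != ncol(r))
    stop("y length does not match the number of samples")

  train <- which(!is.na(y))
  if (length(train) < minTrain)
    stop(sprintf("only %d non-missing values; at least %d required",
                 length(train), minTrain))
  yt <- y[train]
  if (sd(yt) == 0) stop("phenotype is constant on the training samples")
  xt <- t(r[, train, drop = FALSE])

  grid <- .lambdaGrid(xt, yt, alpha, nLambda, lambdaMinRatio)
  foldid <- if (identical(folds, "loo")) seq_along(yt)
            else rep_len(seq_len(as.integer(folds)), length(yt))
  cv <- glmnet::cv.glmnet(xt, yt, alpha = alpha, lambda = grid,
                          foldid = foldid,
                          grouped = !identical(folds, "loo"),
                          standardize = TRUE, family = "gaussian")
  sel <- if (lambdaRule == "min") cv$lambda.min else cv$lambda.1se
  i <- which.min(abs(cv$lambda - sel))
  cvMse <- cv$cvm[i]
  co <- coef(cv$glmnet.fit, s = cv$lambda[i], exact = FALSE)
  w <- as.numeric(co)[-1]
  names(w) <- rownames(co)[-1]
  new("SignatureModel",
      variable = "y", weights = w[w != 0], intercept = as.numeric(co[1]),
      alpha = alpha, lambda = cv$lambda[i], cvMse = cvMse,
      cvMseSd = cv$cvsd[i], r2 = 1 - cvMse / var(yt),
      nTrain = length(train),
      geneSubset = if (is.null(geneSubset)) character() else found)
}

#' Fit signature models for every phenotype variable
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param expr an \linkS4class{ExpressionMatrix} with a \code{resid}
#'   assay.
#' @param ... passed to \code{\link{fitSignature}}.
#' @return a named list of \linkS4class{SignatureModel} (variables whose
#'   fit failed, e.g. too few measurements, are dropped with a message).
#' @export
fitAllSignatures <- function(pheno, expr, ...) {
  df <- phenoValues(pheno)
  out <- list()
  for (v in colnames(df)) {
    y <- setNames(df[[v]], rownames(df))
    fit <- tryCatch(fitSignature(y, expr, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      message("skipping '", v, "': ", conditionMessage(fit))
      next
    }
    fit@variable <- v
    out[[v]] <- fit
  }
  out
}

#' Impute (denoise) signatures across a cohort
#'
#' Applies each model's linear predictor to every sample, including the
#' samples the model was trained on: the predicted value replaces the
#' measured one (denoising), so all samples carry the same
#' model-filtered version of the variable. Models are flagged selected
#' when their cross-validated r2 reaches \code{r2Threshold} (default:
#' at least 1\% of variance explained).
#'
#' @param models list of \linkS4class{SignatureModel}.
#' @param expr an \linkS4class{ExpressionMatrix} whose \code{resid}
#'   assay covers all cohort samples.
#' @param r2Threshold selection threshold on cross-validated r2.
#' @return a \linkS4class{SignatureMatrix}.
#' @export
imputeSignatures <- function(models, expr, r2Threshold = 0.01) {
  r <- residMatrix(expr)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m@variable, character(1))
  vals <- vapply(models, function(m) {
    w <- signatureWeights(m)
    miss <- setdiff(names(w), rownames(r))
    if (length(miss))
      stop("model '", m@variable, "' references gene(s) absent from the ",
           "expression matrix: ", paste(head(miss, 5), collapse = ", "))
    if (length(w))
      m@intercept + as.numeric(crossprod(r[names(w), , drop = FALSE], w))
    else rep(m@intercept, ncol(r))
  }, numeric(ncol(r)))
  rownames(vals) <- colnames(r)
  sel <- vapply(models, function(m) m@r2 >= r2Threshold, logical(1))
  new("SignatureMatrix", values = vals, selected = sel,
      models = unname(models), r2Threshold = r2Threshold)
}

#' Compare an unrestricted signature with a gene-panel-restricted one
#'
#' Fits the signature twice, once on all expressed genes and once
#' restricted to a fixed panel (e.g. the 53-gene conserved
#' transcriptional response to adversity), and reports both
#' cross-validated r2 values together with how many panel genes were
#' measurable.
#'
#' @param y phenotype vector (named by sample, \code{NA} = unmeasured).
#' @param expr an \linkS4class{ExpressionMatrix} with \code{resid}.
#' @param geneSubset the restricted gene panel.
#' @param ... passed to \code{\link{fitSignature}}.
#' @return a list with \code{r2Full}, \code{r2Restricted},
#'   \code{nSubsetFound}, \code{full} and \code{restricted} models.
#' @export
compareRestricted <- function(y, expr, geneSubset, ...) {
  full <- fitSignature(y, expr, ...)
  restricted <- fitSignature(y, expr, geneSubset = geneSubset, ...)
  list(r2Full = full@r2, r2Restricted = restricted@r2,
       nSubsetFound = length(restricted@geneSubset),
       full = full, restricted = restricted)
}

#' Pairwise correlations between selected signatures
#'
#' Pearson correlation and two-sided p-value for every pair of selected
#' signatures; pairs with p above \code{pMask} are flagged masked (the
#' convention used for correlation heatmaps where nonsignificant cells
#' are blanked).
#'
#' @param sig a \linkS4class{SignatureMatrix}.
#' @param pMask masking threshold (default 0.05).
#' @param selectedOnly restrict to selected signatures (default TRUE).
#' @return list with matrices \code{r}, \code{p}, \code{masked} and the
#'   sample size \code{n}.
#' @export
correlateSignatures <- function(sig, pMask = 0.05, selectedOnly = TRUE) {
  v <- signatureValues(sig)
  if (selectedOnly) v <- v[, selectedSignatures(sig), drop = FALSE]
  if (ncol(v) < 2)
    stop("at least two selected signatures are required")
  n <- nrow(v)
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    warning("constant signature column(s) masked: ",
            paste(colnames(v)[sds == 0], collapse = ", "))
  r <- suppressWarnings(cor(v))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(r) <- 1; diag(p) <- 0
  r[is.na(r)] <- NA; p[!is.finite(p)] <- NA
  masked <- is.na(p) | p > pMask
  list(r = r, p = p, masked = masked, n = n)
}

#' Longitudinal validation of a signature
#'
#' Spearman correlation between the observed change of a variable
#' across two waves and the change of its imputed signature, over the
#' samples measured in both waves. The wave-2 signature must be imputed
#' from expression samples that were not in the training set, so
#' agreement is an out-of-sample check that the signature tracks the
#' phenotype over time.
#'
#' @param obs1,obs2 observed values per wave, named by sample.
#' @param sig1,sig2 imputed signature values per wave, named by sample.
#' @return list with \code{rho}, \code{p} and the number of paired
#'   samples \code{n}.
#' @export
validateLongitudinal <- function(obs1, obs2, sig1, sig2) {
  common <- Reduce(intersect, list(names(obs1), names(obs2),
                                   names(sig1), names(sig2)))
  ok <- common[!is.na(obs1[common]) & !is.na(obs2[common]) &
               !is.na(sig1[common]) & !is.na(sig2[common])]
  if (length(ok) < 5)
    stop("fewer than 5 samples observed in both waves")
  dObs <- obs2[ok] - obs1[ok]
  dSig <- sig2[ok] - sig1[ok]
  ct <- suppressWarnings(cor.test(dObs, dSig, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(ok))
}

#' The 53-gene conserved transcriptional response to adversity panel
#'
#' Gene symbols of the published CTRA contrast: 19 pro-inflammatory
#' genes scored positively, 34 type-I-interferon and antibody-synthesis
#' genes scored negatively. Used as the restricted panel in
#' \code{\link{compareRestricted}}.
#'
#' @return character vector of 53 gene symbols.
#' @export
ctraGenes <- function() {
  path <- system.file("extdata", "ctra_genes.txt", package = "sigQTL",
                      mustWork = TRUE)
  readLines(path)
}
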