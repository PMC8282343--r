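## Gene filtering, log2-CPM normalization, confounder PCs and
## residualization.

.SEX_CHROMS <- c("X", "Y", "chrX", "chrY")

#' Filter lowly expressed and sex-chromosome genes
#'
#' Sex-chromosome genes are removed first. A remaining gene is kept when
#' it reaches both \code{minCount} reads and \code{minCpm} counts per
#' million in strictly more than \code{minFraction} of samples;
#' equivalently, a gene falling below either threshold in at least
#' \code{1 - minFraction} of samples is dropped (a gene exactly at the
#' boundary is dropped). Gene order is preserved.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with raw counts.
#' @param minCount minimum read count (default 6).
#' @param minCpm minimum counts per million (default 0.1).
#' @param minFraction fraction of samples that must pass (default 0.8,
#'   strict inequality).
#' @return the filtered \linkS4class{ExpressionMatrix}.
#' @examples
#' co <- simCohort(simConfig(nSamples = 30, nGenes = 80, nVariants = 160))
#' kept <- filterGenes(co@expression)
#' nrow(kept) <= nrow(co@expression)
#' @export
filterGenes <- function(expr, minCount = 6, minCpm = 0.1,
                        minFraction = 0.8) {
  autosomal <- !(as.character(rowData(expr)$chrom) %in% .SEX_CHROMS)
  expr <- expr[autosomal, ]
  cts <- counts(expr)
  libsize <- colSums(cts)
  if (any(libsize <= 0))
    stop("library size is zero for sample(s): ",
         paste(colnames(cts)[libsize <= 0], collapse = ", "))
  cpm <- sweep(cts, 2, libsize / 1e6, "/")
  pass <- (cts >= minCount) & (cpm >= minCpm)
  keep <- rowMeans(pass) > minFraction
  if (!any(keep))
    stop("no genes pass the expression filter")
  expr[keep, ]
}

#' Log2 counts-per-million normalization
#'
#' \code{log2((count + priorCount) / (libsize + 1) * 1e6)} with library
#' sizes taken as column sums of the (filtered) counts. The 0.5 prior
#' count and +1 library-size offset keep zeros finite while perturbing
#' well-expressed genes negligibly. Precision weights are intentionally
#' not computed: downstream fits are unweighted.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param priorCount pseudo-count added to every count (default 0.5).
#' @return the input with a \code{logcpm} assay added.
#' @export
normalizeLogCpm <- function(expr, priorCount = 0.5) {
  cts <- counts(expr)
  libsize <- colSums(cts)
  if (any(libsize == 0))
    stop("library size is zero for sample(s): ",
         paste(colnames(cts)[libsize == 0], collapse = ", "))
  lc <- log2(sweep(cts + priorCount, 2, (libsize + 1) / 1e6, "/"))
  assay(expr, "logcpm") <- lc
  expr
}

## One-hot encode categoricals (first level dropped), median-impute
## missing numeric values, z-score, drop constants with a warning.
.encodeCovariates <- function(raw) {
  stopifnot(is.data.frame(raw))
  num <- lapply(names(raw), function(nm) {
    v <- raw[[nm]]
    if (is.numeric(v)) {
      if (anyNA(v)) v[is.na(v)] <- median(v, na.rm = TRUE)
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      m <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
    }
    m
  })
  m <- do.call(cbind, num)
  rownames(m) <- rownames(raw)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(m)
}

#' Principal components of a covariate matrix
#'
#' Encodes categorical covariates as indicators (first level dropped),
#' median-imputes missing values, z-scores every column and returns the
#' top \code{k} principal components with their fraction of variance
#' explained. A handful of PCs typically captures nearly all covariate
#' variance because technical covariates are strongly collinear.
#'
#' @param cov a \linkS4class{CovariateSet} (or data.frame).
#' @param k number of components (default 3).
#' @return a \linkS4class{CovariateSet} with \code{pcs} and
#'   \code{varianceExplained} filled in.
#' @export
covariatePCs <- function(cov, k = 3) {
  raw <- if (is(cov, "CovariateSet")) cov@raw else as.data.frame(cov)
  m <- .encodeCovariates(raw)
  k <- min(k, ncol(m), nrow(m) - 1L)
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(raw)
  new("CovariateSet", raw = raw, pcs = scores,
      varianceExplained = ve[seq_len(k)])
}

## Resolve a covariate argument to a numeric design matrix (no
## intercept column; the caller adds it).
.covariateDesign <- function(cov, sampleIds) {
  m <- if (is(cov, "CovariateSet")) {
    if (ncol(cov@pcs)) cov@pcs else .encodeCovariates(cov@raw)
  } else if (is.data.frame(cov)) {
    .encodeCovariates(cov)
  } else as.matrix(cov)
  default <- identical(rownames(m), as.character(seq_len(nrow(m))))
  if (!is.null(rownames(m)) && !default && !is.null(sampleIds)) {
    if (!all(sampleIds %in% rownames(m)))
      stop("covariates are missing sample(s): ",
           paste(head(setdiff(sampleIds, rownames(m)), 5), collapse = ", "))
    m <- m[sampleIds, , drop = FALSE]
  } else if (nrow(m) != length(sampleIds))
    stop("covariate rows do not match the expression samples")
  m
}

#' Residualize expression against covariates
#'
#' Per gene, ordinary least squares of log2-CPM on an intercept plus the
#' covariates; the residuals (zero-mean by construction) become the
#' \code{resid} assay that all association testing runs on.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with a \code{logcpm}
#'   assay.
#' @param cov a \linkS4class{CovariateSet}, data.frame or numeric
#'   matrix; a \code{CovariateSet} contributes its PCs when computed,
#'   otherwise its encoded raw columns.
#' @param useAssay assay to residualize (default \code{"logcpm"}).
#' @return the input with a \code{resid} assay added.
#' @export
residualize <- function(expr, cov, useAssay = "logcpm") {
  y <- assay(expr, useAssay)
  x <- .covariateDesign(cov, colnames(y))
  X <- cbind(`(Intercept)` = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  assay(expr, "resid") <- t(qr.resid(qrX, t(y)))
  expr
}
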