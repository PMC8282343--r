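## cis-eQTL mapping on residualized expression: candidate selection in
## a window around the strand-aware TSS, per-variant OLS nominal scan,
## adaptive permutations of the expression vector with a beta
## approximation of the minimum-p null, and gene-level Storey FDR.

#' Create a cis-scan configuration
#'
#' Defaults follow common practice for modest cohorts: a 1 Mb window
#' around the TSS, cohort MAF strictly above 0.1, adaptive permutations
#' between 1,000 and 10,000, and a 10\% gene-level FDR.
#'
#' @param windowBp cis window, inclusive (default 1e6).
#' @param mafMin MAF threshold, strict (default 0.1).
#' @param permMin,permMax adaptive permutation bounds.
#' @param adaptiveStopHits stop once this many permutation minima beat
#'   the observed minimum (default 100).
#' @param fdrLevel gene-level FDR for eGene calls (default 0.10).
#' @param nExpressionPCs expression PCs appended to the residualization
#'   (default 0).
#' @param seed seed for gene-indexed permutation streams.
#' @return a \linkS4class{CisScanConfig}.
#' @export
cisScanConfig <- function(windowBp = 1e6, mafMin = 0.1, permMin = 1000,
                          permMax = 10000, adaptiveStopHits = 100,
                          fdrLevel = 0.10, nExpressionPCs = 0,
                          seed = 1) {
  new("CisScanConfig", windowBp = as.numeric(windowBp),
      mafMin = as.numeric(mafMin), permMin = as.integer(permMin),
      permMax = as.integer(permMax),
      adaptiveStopHits = as.integer(adaptiveStopHits),
      fdrLevel = as.numeric(fdrLevel),
      nExpressionPCs = as.integer(nExpressionPCs),
      seed = as.integer(seed))
}

.normChrom <- function(x) sub("^chr", "", as.character(x))

#' Cohort minor allele frequency from dosages
#'
#' \code{min(m, 1 - m)} with \code{m = mean(dosage) / 2} over
#' non-missing samples.
#'
#' @param d dosage vector or variants x samples matrix.
#' @return MAF per variant.
#' @export
cohortMaf <- function(d) {
  m <- if (is.matrix(d)) rowMeans(d, na.rm = TRUE) / 2
       else mean(d, na.rm = TRUE) / 2
  pmin(m, 1 - m)
}

#' Candidate cis variants for a gene
#'
#' Variants on the gene's chromosome within \code{windowBp} of its TSS
#' (inclusive on both sides) and with cohort MAF strictly above
#' \code{mafMin}. The TSS is strand-aware: annotation readers store the
#' transcription start, i.e. the end coordinate for minus-strand genes.
#' Chromosome names are compared after stripping any "chr" prefix.
#'
#' @param gene gene id.
#' @param annotation data.frame with \code{gene_id}, \code{chrom},
#'   \code{tss} (and optionally \code{strand}), or an
#'   \linkS4class{ExpressionMatrix}.
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param config a \linkS4class{CisScanConfig}.
#' @return data.frame of candidate variants (id, chrom, pos, maf,
#'   tssDistance).
#' @export
cisCandidates <- function(gene, annotation, genotypes, config) {
  ann <- if (is(annotation, "ExpressionMatrix")) geneInfo(annotation)
         else annotation
  row <- ann[ann$gene_id == gene, , drop = FALSE]
  if (!nrow(row)) stop("gene '", gene, "' is absent from the annotation")
  vi <- variantInfo(genotypes)
  onChrom <- .normChrom(vi$chrom) == .normChrom(row$chrom[1])
  dist <- vi$pos - row$tss[1]
  inWin <- onChrom & abs(dist) <= config@windowBp
  if (!any(inWin))
    return(data.frame(id = character(), chrom = character(),
                      pos = numeric(), maf = numeric(),
                      tssDistance = numeric()))
  maf <- cohortMaf(dosages(genotypes)[inWin, , drop = FALSE])
  keep <- maf > config@mafMin
  data.frame(id = vi$id[inWin][keep], chrom = vi$chrom[inWin][keep],
             pos = vi$pos[inWin][keep], maf = maf[keep],
             tssDistance = dist[inWin][keep],
             stringsAsFactors = FALSE)
}

#' Per-variant nominal association scan
#'
#' Simple OLS of residualized expression on dosage (intercept included)
#' for each variant, with a two-sided t-test on the slope at n - 2
#' degrees of freedom. Zero-variance variants are skipped with a flag.
#'
#' @param y residualized expression vector.
#' @param D samples x variants dosage matrix (or a vector).
#' @return data.frame with \code{variant}, \code{slope}, \code{se},
#'   \code{p} and \code{skipped}.
#' @export
nominalScan <- function(y, D) {
  if (!is.matrix(D)) D <- matrix(D, ncol = 1)
  n <- length(y)
  if (nrow(D) != n) stop("dosage rows must match the expression samples")
  if (n < 10) stop("at least 10 samples are required")
  y0 <- y - mean(y)
  D0 <- sweep(D, 2, colMeans(D))
  sxx <- colSums(D0^2)
  skipped <- sxx == 0
  sxy <- as.numeric(crossprod(D0, y0))
  slope <- ifelse(skipped, NA_real_, sxy / sxx)
  syy <- sum(y0^2)
  sse <- pmax(syy - slope^2 * sxx, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- slope / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!skipped & se == 0] <- 0 # exact fit
  data.frame(variant = colnames(D) %||% seq_len(ncol(D)),
             slope = slope, se = se, p = p, skipped = skipped,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Beta(a, b) maximum likelihood on values in (0, 1): method-of-moments
## start, then box-constrained quasi-Newton on the log parameters.
## Falls back to the moments estimate (flagged) when optimization fails.
.fitBeta <- function(x, lower = 1e-3, upper = 1e6) {
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- var(x)
  v <- min(max(v, 1e-12), m * (1 - m) * (1 - 1e-8))
  k <- m * (1 - m) / v - 1
  start <- pmin(pmax(c(m * k, (1 - m) * k), lower), upper)
  nll <- function(lp) -sum(dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- tryCatch(
    optim(log(start), nll, method = "L-BFGS-B",
          lower = log(lower), upper = log(upper)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    out <- start
    attr(out, "momentsFallback") <- TRUE
    return(out)
  }
  out <- exp(fit$par)
  attr(out, "momentsFallback") <- FALSE
  out
}

## Minimum nominal p over variants for permuted expression vectors.
## Permuting y preserves its mean and norm, so correlations reduce to
## one crossprod of unit-norm centered matrices per chunk.
.permMinP <- function(y, D, nPerm, df) {
  n <- length(y)
  y0 <- y - mean(y)
  y0 <- y0 / sqrt(sum(y0^2))
  D0 <- sweep(D, 2, colMeans(D))
  nrm <- sqrt(colSums(D0^2))
  ok <- nrm > 0
  D0 <- sweep(D0[, ok, drop = FALSE], 2, nrm[ok], "/")
  P <- vapply(seq_len(nPerm), function(i) y0[sample.int(n)],
              numeric(n))
  r2 <- apply(crossprod(D0, P)^2, 2, max)
  r2 <- pmin(r2, 1 - 1e-14)
  2 * pt(-sqrt(df * r2 / (1 - r2)), df = df)
}

#' Permutation pass for one gene
#'
#' Shuffles the expression vector (dosages fixed), records the minimum
#' nominal p over the candidate variants per permutation, and stops
#' adaptively: after \code{permMin} permutations, permuting continues
#' in blocks until either \code{adaptiveStopHits} permutation minima
#' have beaten the observed minimum or \code{permMax} is reached.
#'
#' Two gene-level empirical p-values are returned: the direct estimate
#' \code{(1 + hits) / (1 + P)} and a smooth estimate from a Beta(a, b)
#' maximum-likelihood fit to the permutation minima, evaluated as
#' \code{pbeta(observed minimum)}. For a single candidate variant the
#' minimum of one uniform p-value is uniform, so the fitted shape
#' parameters approach (1, 1); for m independent variants the null
#' minimum is approximately Beta(1, m).
#'
#' @param y residualized expression vector.
#' @param D samples x variants dosage matrix.
#' @param config a \linkS4class{CisScanConfig}.
#' @param tssDistance per-variant signed distance to the TSS (used in
#'   the lead tie-break; optional).
#' @param seed per-gene stream seed (default from config).
#' @return list with the observed scan and permutation summaries.
#' @export
permutationPass <- function(y, D, config = cisScanConfig(),
                            tssDistance = NULL, seed = config@seed) {
  if (!is.matrix(D)) D <- matrix(D, ncol = 1,
                                 dimnames = list(NULL, "v1"))
  obs <- nominalScan(y, D)
  usable <- which(!obs$skipped)
  if (!length(usable)) stop("no candidate variant has dosage variance")
  ## lead tie-break: smallest p, then smallest |tssDistance|, then id
  dist <- if (is.null(tssDistance)) rep(NA_real_, ncol(D)) else tssDistance
  o <- order(obs$p[usable], abs(dist[usable]), obs$variant[usable])
  best <- usable[o[1]]
  obsMin <- obs$p[best]
  n <- length(y); df <- n - 2

  set.seed(seed)
  minima <- .permMinP(y, D, config@permMin, df)
  block <- min(1000L, config@permMin)
  while (sum(minima <= obsMin) < config@adaptiveStopHits &&
         length(minima) < config@permMax) {
    take <- min(block, config@permMax - length(minima))
    minima <- c(minima, .permMinP(y, D, take, df))
  }
  P <- length(minima)
  if (P < config@permMin)
    stop("fewer than permMin permutations completed")
  hits <- sum(minima <= obsMin)
  shape <- .fitBeta(minima)
  list(permPDirect = (1 + hits) / (1 + P),
       permPBeta = pbeta(obsMin, shape[1], shape[2]),
       betaShape1 = shape[1], betaShape2 = shape[2],
       momentsFallback = isTRUE(attr(shape, "momentsFallback")),
       bestVariant = obs$variant[best], bestIndex = best,
       nominalP = obsMin, slope = obs$slope[best],
       nPerm = P, permMinima = minima)
}

#' Map cis-eQTLs across all genes
#'
#' Runs candidate selection, the nominal scan and the adaptive
#' permutation pass for every annotated gene with at least one
#' candidate variant, then attaches gene-level Storey q-values over the
#' beta-approximated permutation p-values. Per-gene permutation streams
#' are seeded from the configuration seed, so results do not depend on
#' gene or variant input order.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with a \code{resid}
#'   assay.
#' @param genotypes a \linkS4class{GenotypeMatrix} over the same
#'   samples.
#' @param config a \linkS4class{CisScanConfig}.
#' @param keepMinima keep each gene's permutation minima (for
#'   diagnostics; default FALSE).
#' @return data.frame with one row per tested gene: \code{gene},
#'   \code{nVariants}, \code{betaShape1}, \code{betaShape2},
#'   \code{dummy}, \code{bestVariant}, \code{tssDistance},
#'   \code{nominalP}, \code{slope}, \code{permPDirect},
#'   \code{permPBeta}, plus \code{qvalue} and \code{eGene}.
#' @export
mapCisEqtl <- function(expr, genotypes, config = cisScanConfig(),
                       keepMinima = FALSE) {
  r <- residMatrix(expr)
  samples <- colnames(r)
  if (!all(samples %in% colnames(genotypes)))
    stop("genotypes do not cover all expression samples")
  gt <- genotypes[, samples]
  ann <- geneInfo(expr)
  dos <- t(dosages(gt)) # samples x variants
  set.seed(config@seed)
  geneSeeds <- sample.int(.Machine$integer.max - 1L, nrow(ann))
  names(geneSeeds) <- sort(ann$gene_id)

  rows <- vector("list", nrow(ann))
  minima <- list()
  for (i in seq_len(nrow(ann))) {
    g <- ann$gene_id[i]
    cand <- cisCandidates(g, ann, gt, config)
    if (!nrow(cand)) next
    D <- dos[, cand$id, drop = FALSE]
    pp <- permutationPass(r[g, ], D, config,
                          tssDistance = cand$tssDistance,
                          seed = geneSeeds[[g]])
    rows[[i]] <- data.frame(
      gene = g, nVariants = nrow(cand),
      betaShape1 = pp$betaShape1, betaShape2 = pp$betaShape2,
      dummy = 0L, bestVariant = pp$bestVariant,
      tssDistance = cand$tssDistance[pp$bestIndex],
      nominalP = pp$nominalP, slope = pp$slope,
      permPDirect = pp$permPDirect, permPBeta = pp$permPBeta,
      stringsAsFactors = FALSE)
    if (keepMinima) minima[[g]] <- pp$permMinima
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no gene had candidate cis variants")
  rownames(out) <- NULL
  out <- geneFdr(out, config@fdrLevel)
  if (keepMinima) attr(out, "permMinima") <- minima
  out
}

#' Gene-level FDR over permutation p-values
#'
#' Storey q-values over the beta-approximated permutation p-values;
#' genes at \code{qvalue <= fdrLevel} are flagged eGenes.
#'
#' @param records output of \code{\link{mapCisEqtl}} (needs a
#'   \code{permPBeta} column).
#' @param fdrLevel FDR threshold (default 0.10).
#' @param pi0 optional fixed null proportion (see
#'   \code{\link{storeyQvalue}}).
#' @return the records with \code{qvalue} and \code{eGene} columns.
#' @export
geneFdr <- function(records, fdrLevel = 0.10, pi0 = NULL) {
  if (any(records$permPBeta < 0 | records$permPBeta > 1, na.rm = TRUE))
    stop("permutation p-values outside [0, 1]")
  q <- storeyQvalue(records$permPBeta, pi0 = pi0)
  records$qvalue <- as.numeric(q)
  records$eGene <- records$qvalue <= fdrLevel
  attr(records, "pi0") <- attr(q, "pi0")
  records
}

#' Optimize the number of expression PCs for eGene discovery
#'
#' For each candidate k, the top-k principal components of the
#' residualized expression are appended to the residualization and the
#' full permutation pass is rerun; the k maximizing the number of
#' eGenes is chosen (ties resolved toward the smallest k). Hidden
#' expression-wide confounders mask cis effects, so eGene counts
#' typically rise with k up to an optimum.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with a \code{resid}
#'   assay.
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param config a \linkS4class{CisScanConfig}.
#' @param pcGrid nonnegative integers to try.
#' @return list with \code{chosenK}, \code{eGeneCounts} (named by k)
#'   and \code{records} for the chosen k.
#' @export
optimizeExpressionPCs <- function(expr, genotypes,
                                  config = cisScanConfig(),
                                  pcGrid = c(0, 1, 2, 5)) {
  pcGrid <- sort(unique(as.integer(pcGrid)))
  if (any(pcGrid < 0)) stop("pcGrid must be nonnegative")
  base <- residMatrix(expr)
  if (any(pcGrid >= ncol(base)))
    stop("number of expression PCs must be below the sample count")
  pcAll <- prcomp(t(base), center = TRUE, scale. = FALSE)$x
  counts <- setNames(integer(length(pcGrid)), pcGrid)
  recordsByK <- vector("list", length(pcGrid))
  for (j in seq_along(pcGrid)) {
    k <- pcGrid[j]
    e <- expr
    if (k > 0) {
      X <- cbind(1, pcAll[, seq_len(k), drop = FALSE])
      assay(e, "resid") <- t(qr.resid(qr(X), t(base)))
    }
    cfg <- config
    cfg@nExpressionPCs <- k
    rec <- mapCisEqtl(e, genotypes, cfg)
    counts[j] <- sum(rec$eGene)
    recordsByK[[j]] <- rec
  }
  chosen <- which.max(counts) # ties: first (smallest k) wins
  list(chosenK = pcGrid[chosen], eGeneCounts = counts,
       records = recordsByK[[chosen]])
}
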