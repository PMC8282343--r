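## Interaction (GxE) eQTL mapping: per lead gene-variant pair, OLS of
## residualized expression on dosage, a quantile-normalized
## environment and their product; empirical correction against a
## pooled permutation null; Storey q-values within each signature.

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles through their ranks using
#' the Blom offset \code{(rank - 3/8) / (n + 1/4)}; ties get average
#' ranks and \code{NA}s are preserved. Applied to each transcriptional
#' signature before GxE testing to blunt the influence of outliers; the
#' output is invariant to any strictly monotone transform of the input.
#'
#' @param x numeric vector (at least 3 finite values).
#' @return transformed vector of the same length and names.
#' @examples
#' inverseNormalTransform(c(5, 1, 9))
#' @export
inverseNormalTransform <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 3) stop("at least 3 finite values are required")
  if (length(unique(x[obs])) == 1L)
    stop("all values are identical; rank-normal scores are undefined")
  out <- rep(NA_real_, length(x))
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  names(out) <- names(x)
  out
}

.GXE_TERMS <- c("intercept", "dosage", "signature", "interaction")

#' Fit the interaction model for one gene-variant-environment triple
#'
#' \code{expression ~ dosage + environment + dosage:environment}, with
#' optional covariates (e.g. the four cell-composition signatures)
#' entering as main effects. Fitted with \code{\link[stats]{lm}};
#' estimates, standard errors and two-sided t p-values are reported for
#' the intercept, dosage, environment and interaction terms.
#'
#' @param exprG residualized expression vector for one gene.
#' @param dosage dosage vector for the lead variant.
#' @param env environment vector (quantile-normalize signatures with
#'   \code{\link{inverseNormalTransform}} first).
#' @param covariates optional samples x covariates matrix.
#' @return one-row data.frame with \code{p_}, \code{b_} and \code{se_}
#'   columns for the four named terms, plus \code{n}.
#' @export
fitInteraction <- function(exprG, dosage, env, covariates = NULL) {
  n <- length(exprG)
  if (length(dosage) != n || length(env) != n)
    stop("expression, dosage and environment lengths differ")
  keep <- !(is.na(exprG) | is.na(dosage) | is.na(env))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & !rowSums(is.na(covariates))
  }
  df <- data.frame(y = exprG[keep], dosage = dosage[keep],
                   env = env[keep])
  fml <- y ~ dosage + env + dosage:env
  if (!is.null(covariates)) {
    cv <- covariates[keep, , drop = FALSE]
    colnames(cv) <- paste0("cov_", seq_len(ncol(cv)))
    df <- cbind(df, cv)
    fml <- stats::as.formula(paste(
      "y ~", paste(colnames(cv), collapse = " + "),
      "+ dosage + env + dosage:env"))
  }
  fit <- lm(fml, data = df)
  cf <- coef(fit)
  want <- c("(Intercept)", "dosage", "env", "dosage:env")
  if (anyNA(cf[want])) {
    bad <- .GXE_TERMS[is.na(cf[want])]
    stop("interaction design is rank deficient; offending term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients[want, , drop = FALSE]
  out <- data.frame(t(c(sm[, 4], sm[, 1], sm[, 2])), n = nrow(df))
  names(out) <- c(paste0("p_", .GXE_TERMS), paste0("b_", .GXE_TERMS),
                  paste0("se_", .GXE_TERMS), "n")
  out
}

## Batch interaction fits for one (y, env) pair against many dosage
## columns, via closed-form cross-products: used for the permutation
## null where millions of refits are needed. Returns the interaction
## p-value (and optionally estimate/SE) per column of D.
.interactionScan <- function(y, env, D, full = FALSE) {
  n <- length(y)
  B <- ncol(D)
  e <- env
  D2 <- D * D
  sD <- colSums(D); sD2 <- colSums(D2)
  sDe <- as.numeric(crossprod(D, e))
  sD2e <- as.numeric(crossprod(D2, e))
  sDe2 <- as.numeric(crossprod(D, e * e))
  sD2e2 <- as.numeric(crossprod(D2, e * e))
  sDy <- as.numeric(crossprod(D, y))
  sDey <- as.numeric(crossprod(D, e * y))
  se_ <- sum(e); se2 <- sum(e * e); sy <- sum(y); sey <- sum(e * y)
  yy <- sum(y * y)
  dfres <- n - 4
  p <- est <- sev <- numeric(B)
  for (b in seq_len(B)) {
    A <- matrix(c(n,      sD[b],   se_,     sDe[b],
                  sD[b],  sD2[b],  sDe[b],  sD2e[b],
                  se_,    sDe[b],  se2,     sDe2[b],
                  sDe[b], sD2e[b], sDe2[b], sD2e2[b]), 4, 4)
    xty <- c(sy, sDy[b], sey, sDey[b])
    Ai <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
    if (is.null(Ai)) { p[b] <- NA; est[b] <- NA; sev[b] <- NA; next }
    beta <- Ai %*% xty
    sigma2 <- max(yy - sum(beta * xty), 0) / dfres
    s <- sqrt(Ai[4, 4] * sigma2)
    est[b] <- beta[4]; sev[b] <- s
    p[b] <- 2 * pt(-abs(beta[4] / s), df = dfres)
  }
  if (full) data.frame(p = p, b = est, se = sev) else p
}

#' Map interaction eQTLs at lead variants
#'
#' For every signature and every lead gene-variant pair, fits the
#' interaction model on residualized expression. Each signature is
#' quantile-normalized before testing. q-values for all four model
#' terms are computed within each signature across genes.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with \code{resid}.
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param leads data.frame with \code{gene} and \code{bestVariant}
#'   columns (as produced by \code{\link{mapCisEqtl}}; typically its
#'   eGene rows from a scan without expression PCs).
#' @param env samples x signatures matrix (e.g.
#'   \code{signatureValues()}), or a single named vector.
#' @param covariates optional samples x covariates matrix applied to
#'   every fit (e.g. four cell-composition signatures).
#' @param intApplied set TRUE when \code{env} is already
#'   quantile-normalized.
#' @return data.frame of \code{GxeRecord} rows: identifiers, the four
#'   p-values, estimates, SEs and q-values, and the signature name.
#' @export
mapInteractions <- function(expr, genotypes, leads, env,
                            covariates = NULL, intApplied = FALSE) {
  r <- residMatrix(expr)
  samples <- colnames(r)
  dos <- dosages(genotypes[, samples])
  if (is.null(dim(env))) env <- matrix(env, ncol = 1,
                                       dimnames = list(names(env), "env"))
  if (!is.null(rownames(env))) {
    env <- env[samples, , drop = FALSE]
  } else if (nrow(env) != length(samples))
    stop("env rows do not match the expression samples")
  out <- list()
  for (sig in colnames(env)) {
    e <- env[, sig]
    if (!intApplied) e <- inverseNormalTransform(e)
    rows <- lapply(seq_len(nrow(leads)), function(i) {
      g <- leads$gene[i]; v <- leads$bestVariant[i]
      rec <- fitInteraction(r[g, ], dos[v, ], e, covariates = covariates)
      cbind(data.frame(gene = g, variant = v,
                       stringsAsFactors = FALSE), rec)
    })
    tab <- do.call(rbind, rows)
    for (term in .GXE_TERMS)
      tab[[paste0("q_", term)]] <-
        as.numeric(storeyQvalue(tab[[paste0("p_", term)]]))
    tab$signature <- sig
    out[[sig]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a pooled permutation null for interaction p-values
#'
#' Repeatedly permutes the genotype dosages (keeping the
#' expression-environment pairing intact), refits the interaction model
#' for every lead pair, and pools the interaction p-values until
#' \code{nNull} values are collected. The pooled-within-signature null
#' is what the empirical correction of observed interaction p-values is
#' computed against; it should be large relative to the number of
#' observed tests (ten-fold or more).
#'
#' @param expr an \linkS4class{ExpressionMatrix} with \code{resid}.
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param leads data.frame with \code{gene} and \code{bestVariant}.
#' @param env signature vector over samples (quantile-normalized unless
#'   \code{intApplied = FALSE}).
#' @param nNull number of null values to collect.
#' @param seed RNG seed (the store records it).
#' @param signatureName label stored with the null.
#' @param intApplied set TRUE when \code{env} is already
#'   quantile-normalized.
#' @return a \linkS4class{NullStore}.
#' @export
buildPermutationNull <- function(expr, genotypes, leads, env,
                                 nNull = 1e6, seed = 1,
                                 signatureName = "signature",
                                 intApplied = FALSE) {
  if (nNull < 1) stop("nNull must be positive")
  r <- residMatrix(expr)
  samples <- colnames(r)
  dos <- dosages(genotypes[, samples])
  if (!is.null(names(env))) env <- env[samples]
  if (!intApplied) env <- inverseNormalTransform(env)
  nLeads <- nrow(leads)
  if (nNull < 10 * nLeads)
    warning("nNull is below 10x the number of observed tests; ",
            "the empirical correction will be coarse")
  rounds <- ceiling(nNull / nLeads)
  n <- length(samples)
  set.seed(seed)
  pooled <- vector("list", nLeads)
  for (i in seq_len(nLeads)) {
    y <- r[leads$gene[i], ]
    d <- dos[leads$bestVariant[i], ]
    Dp <- vapply(seq_len(rounds), function(b) d[sample.int(n)],
                 numeric(n))
    pooled[[i]] <- .interactionScan(y, env, Dp)
  }
  ## interleave by round so truncation keeps complete rounds
  m <- do.call(rbind, pooled) # leads x rounds
  vals <- as.numeric(m)[seq_len(nNull)]
  vals <- vals[!is.na(vals)]
  new("NullStore", signature = signatureName, nullP = vals,
      nNull = length(vals), seed = as.integer(seed))
}

#' Empirical correction and q-values for interaction p-values
#'
#' Each observed interaction p-value is converted to an empirical
#' p-value against the pooled permutation null,
#' \code{(1 + #\{null <= p\}) / (1 + nNull)}, and Storey q-values are
#' computed over the corrected values within the signature.
#'
#' @param records \code{GxeRecord} rows for one signature (from
#'   \code{\link{mapInteractions}}).
#' @param nullStore the matching \linkS4class{NullStore}.
#' @param fdrLevel significance threshold on the q-values.
#' @param pi0 optional fixed null proportion.
#' @return records with \code{p_interaction_permcorrected},
#'   \code{q_interaction_permcorrected} and \code{significant} columns.
#' @export
correctAndQvalue <- function(records, nullStore, fdrLevel = 0.10,
                             pi0 = NULL) {
  if (!nullStore@nNull) stop("the null store is empty")
  if (!is.null(records$signature) &&
      !all(records$signature == nullStore@signature))
    stop("null store signature '", nullStore@signature,
         "' does not match the records")
  srt <- sort(nullValues(nullStore))
  hits <- findInterval(records$p_interaction, srt)
  pc <- (1 + hits) / (1 + nullStore@nNull)
  records$p_interaction_permcorrected <- pc
  q <- storeyQvalue(pc, pi0 = pi0)
  records$q_interaction_permcorrected <- as.numeric(q)
  records$significant <- records$q_interaction_permcorrected <= fdrLevel
  attr(records, "pi0") <- attr(q, "pi0")
  records
}

#' Enrichment of one gene set in another (2x2 Fisher test)
#'
#' Cross-tabulates membership in two gene sets over a common universe
#' and reports the sample odds ratio \code{ad/bc} (with a 0.5
#' continuity correction when any cell is empty, flagged) and the
#' two-sided Fisher exact p-value computed by hypergeometric
#' enumeration: the sum of the probabilities of all tables, at the
#' observed margins, no more probable than the observed one.
#'
#' @param setA,setB gene sets (subsets of \code{universe}).
#' @param universe all eligible genes.
#' @return list with \code{oddsRatio}, \code{p}, the 2x2 \code{table}
#'   and \code{continuityCorrected}.
#' @export
replicationEnrichment <- function(setA, setB, universe) {
  if (!length(universe)) stop("the gene universe is empty")
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  inA <- universe %in% setA
  inB <- universe %in% setB
  a <- sum(inA & inB); b <- sum(inA & !inB)
  c_ <- sum(!inA & inB); d <- sum(!inA & !inB)
  cc <- any(c(a, b, c_, d) == 0)
  orr <- if (cc) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
         else (a * d) / (b * c_)
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("inA", "notA"), c("inB", "notB")))
  list(oddsRatio = orr, p = .fisherP2x2(a, b, c_, d), table = tab,
       continuityCorrected = cc)
}

## Two-sided Fisher p by full hypergeometric enumeration at fixed
## margins (the convention of summing all tables with probability no
## greater than the observed one, within a 1 + 1e-7 relative slack).
.fisherP2x2 <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  pObs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Concordance of interaction effects between two analyses
#'
#' Joins two GxE result tables on (gene, variant, signature), converts
#' each interaction estimate to a z-score \code{b / se} and reports the
#' Pearson correlation of the z-scores. Used to compare interactions
#' detected with measured variables against those detected with their
#' denoised transcriptional signatures.
#'
#' @param recordsA,recordsB GxE record data.frames.
#' @return list with \code{r}, \code{p} and \code{nPairs}.
#' @export
effectConcordance <- function(recordsA, recordsB) {
  key <- function(x) paste(x$gene, x$variant, x$signature, sep = "\r")
  j <- merge(data.frame(k = key(recordsA),
                        zA = recordsA$b_interaction /
                          recordsA$se_interaction),
             data.frame(k = key(recordsB),
                        zB = recordsB$b_interaction /
                          recordsB$se_interaction), by = "k")
  if (nrow(j) < 3) stop("fewer than 3 joined gene-variant-signature pairs")
  ct <- cor.test(j$zA, j$zB)
  list(r = unname(ct$estimate), p = ct$p.value, nPairs = nrow(j))
}

#' Overlap of significant genes with an external TWAS table
#'
#' For each signature, two gene sets are formed: genes whose marginal
#' environment (signature) term is significant at \code{marginalFdr},
#' and genes whose permutation-corrected interaction is significant at
#' \code{fdrLevel}. Each set is intersected with the TWAS-significant
#' genes of every trait.
#'
#' @param records GxE records carrying \code{q_signature} and
#'   \code{q_interaction_permcorrected}.
#' @param twasTable data.frame with \code{gene}, \code{trait} and
#'   logical \code{significant} columns.
#' @param marginalFdr FDR for the marginal environment effect.
#' @param fdrLevel FDR for the interaction effect.
#' @return data.frame with one row per signature x trait x set type:
#'   set sizes, overlap count and the overlapping genes.
#' @export
twasOverlap <- function(records, twasTable, marginalFdr = 0.10,
                        fdrLevel = 0.10) {
  need <- c("gene", "trait", "significant")
  miss <- setdiff(need, names(twasTable))
  if (length(miss))
    stop("twasTable is missing column(s): ", paste(miss, collapse = ", "))
  twasSig <- twasTable[twasTable$significant, , drop = FALSE]
  out <- list()
  for (sig in unique(records$signature)) {
    rec <- records[records$signature == sig, , drop = FALSE]
    sets <- list(
      marginal = unique(rec$gene[rec$q_signature <= marginalFdr]),
      gxe = if ("q_interaction_permcorrected" %in% names(rec))
        unique(rec$gene[rec$q_interaction_permcorrected <= fdrLevel])
      else character())
    for (trait in unique(twasTable$trait)) {
      tg <- twasSig$gene[twasSig$trait == trait]
      for (s in names(sets)) {
        ov <- intersect(sets[[s]], tg)
        out[[length(out) + 1L]] <- data.frame(
          signature = sig, trait = trait, set = s,
          nSet = length(sets[[s]]), nTwas = length(tg),
          nOverlap = length(ov),
          genes = paste(sort(ov), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(signature = character(), trait = character(),
                      set = character(), nSet = integer(),
                      nTwas = integer(), nOverlap = integer(),
                      genes = character()))
  do.call(rbind, out)
}
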