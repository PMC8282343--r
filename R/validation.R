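## Self-contained simulation studies used to validate the method's
## statistical properties: interaction-test calibration, parameter
## recovery, end-to-end FDR control, signature recovery and the beta
## approximation of the permutation null. Each study simulates its own
## cohort under the package's study-design defaults, runs the analysis
## through the public interface and returns the measured quantities.

## A cohort tailored to GxE studies: every gene is an eQTL of its
## assigned cis variant; an optional subset carries a true interaction
## with the single psychosocial variable; expression is confounded by
## the technical axes. Genes failing the expression filter are
## replaced so that exactly nLeads pairs (nTrue of them true) enter.
.gxeStudyCohort <- function(nLeads = 1000, nTrue = 0, n = 250,
                            betaGxe = 0.4, maf = 0.3, seed = 1) {
  nG <- ceiling(nLeads * 1.224) # headroom for sex-chromosome+count filters
  es <- matrix(0, nG, 3)
  es[, 1] <- 0.5 * rep_len(c(1, -1), nG)
  if (nTrue > 0) {
    cand <- seq(5, by = max(2L, nG %/% (1.5 * nTrue)),
                length.out = min(nG %/% 2, ceiling(1.5 * nTrue)))
    es[cand, 2] <- 0.3
    es[cand, 3] <- betaGxe * rep_len(c(1, -1), length(cand))
  }
  cfg <- simConfig(nSamples = n, nGenes = nG, nVariants = nG,
                   mafRange = c(maf, maf), categoryBlocks = c(ses = 1L),
                   effectSizes = es, missingFraction = 0, seed = seed)
  co <- simCohort(cfg)
  expr <- residualize(normalizeLogCpm(filterGenes(co@expression)),
                      covariatePCs(co@covariates@raw))
  truth <- co@truth
  kept <- rownames(expr)
  trueSet <- names(truth@betaGxe)[truth@betaGxe != 0]
  genes <- c(head(intersect(kept, trueSet), nTrue),
             head(setdiff(kept, trueSet), nLeads - nTrue))
  leads <- data.frame(
    gene = genes,
    bestVariant = truth@assignedVariant[match(genes,
                                              names(truth@betaG))],
    stringsAsFactors = FALSE)
  env <- inverseNormalTransform(latentTraits(truth)[, "ses_1"])
  names(env) <- rownames(latentTraits(truth))
  list(expr = expr, genotypes = co@genotypes, leads = leads, env = env,
       isTrue = genes %in% trueSet, truth = truth)
}

#' Calibration study of the interaction test
#'
#' Simulates a cohort with genetic main effects and technical
#' confounding but no true interactions, tests every lead pair against
#' the psychosocial signature, and measures the empirical type-I error
#' at nominal p < 0.05 together with a Kolmogorov-Smirnov uniformity
#' check of the pooled permutation null.
#'
#' The permutation null is not mathematically uniform: the parametric
#' t p-value is an approximation under negative-binomial noise, with
#' CDF deviations of order 0.005 at n = 250 — the reason the pipeline
#' corrects observed p-values against the empirical null rather than
#' trusting uniformity. The default null size (20x the number of
#' tests) gives the KS check power against genuine miscalibration
#' without flagging that intrinsic approximation.
#'
#' @param nLeads number of null lead pairs.
#' @param n cohort size.
#' @param nNull pooled null size for the uniformity check.
#' @param seed study seed.
#' @return list with \code{typeIError}, \code{ksP}, \code{records} and
#'   the \code{nullStore}.
#' @export
gxeCalibrationStudy <- function(nLeads = 1000, n = 250,
                                nNull = 20 * nLeads, seed = 1) {
  st <- .gxeStudyCohort(nLeads = nLeads, nTrue = 0, n = n, seed = seed)
  rec <- mapInteractions(st$expr, st$genotypes, st$leads, st$env,
                         intApplied = TRUE)
  ns <- buildPermutationNull(st$expr, st$genotypes, st$leads, st$env,
                             nNull = nNull, seed = seed + 500,
                             signatureName = "ses_1", intApplied = TRUE)
  ks <- suppressWarnings(stats::ks.test(nullValues(ns), "punif"))
  list(typeIError = mean(rec$p_interaction < 0.05),
       ksP = ks$p.value, records = rec, nullStore = ns)
}

#' Parameter-recovery study of the interaction estimate
#'
#' Repeatedly simulates the interaction model at known coefficients
#' (Gaussian noise, SD 1) and measures the mean interaction estimate
#' and the coverage of its 95\% confidence interval.
#'
#' @param nReps replicates.
#' @param n samples per replicate.
#' @param betaGxe,betaG,betaE,maf true generative values.
#' @param seed study seed.
#' @return list with \code{meanEstimate}, \code{coverage},
#'   \code{betaGxe} and the per-replicate estimates.
#' @export
gxeRecoveryStudy <- function(nReps = 500, n = 250, betaGxe = 0.4,
                             betaG = 0.3, betaE = 0.2, maf = 0.3,
                             seed = 1) {
  set.seed(seed)
  est <- se <- numeric(nReps)
  for (r in seq_len(nReps)) {
    d <- rbinom(n, 2, maf)
    e <- rnorm(n)
    y <- 0.1 + betaG * d + betaE * e + betaGxe * d * e + rnorm(n)
    f <- fitInteraction(y, d, e)
    est[r] <- f$b_interaction
    se[r] <- f$se_interaction
  }
  crit <- stats::qt(0.975, n - 4)
  list(meanEstimate = mean(est),
       coverage = mean(abs(est - betaGxe) <= crit * se),
       betaGxe = betaGxe, estimates = est)
}

#' End-to-end FDR study of the GxE pipeline
#'
#' Simulates cohorts in which a known subset of lead pairs carries a
#' true interaction, runs mapping, the pooled permutation null and the
#' per-signature q-values, and measures the realized false-discovery
#' proportion and power of the declared set at the requested FDR.
#'
#' @param seeds one study per seed; results are averaged.
#' @param nLeads,nTrue lead pairs per study and how many are true.
#' @param betaGxe true interaction effect.
#' @param maf variant allele frequency.
#' @param n cohort size.
#' @param nNull pooled permutation null size.
#' @param fdrLevel declared FDR.
#' @return list with \code{meanFdp}, \code{meanPower} and the
#'   per-seed table.
#' @export
gxeFdrStudy <- function(seeds = 1:5, nLeads = 1000, nTrue = 100,
                        betaGxe = 0.4, maf = 0.3, n = 250,
                        nNull = 1e6, fdrLevel = 0.10) {
  perSeed <- vapply(seeds, function(s) {
    st <- .gxeStudyCohort(nLeads = nLeads, nTrue = nTrue, n = n,
                          betaGxe = betaGxe, maf = maf, seed = s)
    rec <- mapInteractions(st$expr, st$genotypes, st$leads, st$env,
                           intApplied = TRUE)
    rec$signature <- "ses_1"
    ns <- buildPermutationNull(st$expr, st$genotypes, st$leads, st$env,
                               nNull = nNull, seed = s + 500,
                               signatureName = "ses_1",
                               intApplied = TRUE)
    res <- correctAndQvalue(rec, ns, fdrLevel = fdrLevel)
    called <- res$significant
    c(fdp = sum(called & !st$isTrue) / max(1, sum(called)),
      power = sum(called & st$isTrue) / sum(st$isTrue))
  }, numeric(2))
  list(meanFdp = mean(perSeed["fdp", ]),
       meanPower = mean(perSeed["power", ]),
       perSeed = t(perSeed))
}

#' Signature-recovery study
#'
#' Simulates a cohort whose single psychosocial variable drives 20
#' causal genes at a true signal fraction of 0.5 (unit-variance latent,
#' unit-SD measurement noise), fits the elastic-net signature with
#' leave-one-out cross-validation, and measures the cross-validated r2
#' and the correlation between the imputed signature and the latent
#' trait. Optionally repeats the fit on permuted phenotypes (k-fold CV
#' for tractability) to confirm the null distribution of r2.
#'
#' @param n cohort size.
#' @param nGenes simulated genes (before filtering).
#' @param nCausal causal genes.
#' @param betaE per-gene environmental effect on the log mean.
#' @param nNullReps permuted-phenotype refits (0 to skip).
#' @param seed study seed.
#' @return list with \code{r2}, \code{latentCor}, \code{nullR2} and the
#'   fitted model.
#' @export
signatureRecoveryStudy <- function(n = 250, nGenes = 2040, nCausal = 20,
                                   betaE = 0.5, nNullReps = 100,
                                   seed = 1) {
  es <- matrix(0, nGenes, 3)
  es[seq(50, by = nGenes %/% (nCausal + 1),
         length.out = nCausal), 2] <- betaE
  cfg <- simConfig(nSamples = n, nGenes = nGenes, nVariants = nGenes,
                   categoryBlocks = c(ses = 1L), effectSizes = es,
                   missingFraction = 0, noiseSdPhenotype = 1,
                   seed = seed)
  co <- simCohort(cfg)
  expr <- residualize(normalizeLogCpm(filterGenes(co@expression)),
                      covariatePCs(co@covariates@raw))
  ph <- phenoValues(co@phenotypes)
  y <- setNames(ph$ses_1, rownames(ph))
  fit <- fitSignature(y, expr)
  imp <- signatureValues(imputeSignatures(list(fit), expr))[, 1]
  lat <- latentTraits(co@truth)[, "ses_1"]
  nullR2 <- numeric(0)
  if (nNullReps > 0) {
    set.seed(seed + 1000)
    nullR2 <- vapply(seq_len(nNullReps), function(i) {
      yp <- setNames(sample(y), names(y))
      cvR2(fitSignature(yp, expr, folds = 10))
    }, numeric(1))
  }
  list(r2 = cvR2(fit), latentCor = cor(imp, lat), nullR2 = nullR2,
       model = fit)
}

#' Longitudinal-validation study
#'
#' Simulates two waves in which the latent psychosocial variable
#' drifts between time points, trains the signature on wave 1, imputes
#' both waves (wave 2 from expression never seen in training) and
#' measures the Spearman correlation between observed and imputed
#' changes.
#'
#' @param n wave-1 cohort size.
#' @param retention fraction of samples retained at wave 2.
#' @param driftSd latent drift SD between waves.
#' @param noiseSd phenotype measurement noise.
#' @param folds cross-validation folds for the wave-1 fit.
#' @param seed study seed.
#' @return list with \code{rho}, \code{p}, \code{n} and the wave-1 fit.
#' @export
longitudinalRecoveryStudy <- function(n = 251, retention = 0.4,
                                      driftSd = 1, noiseSd = 0.3,
                                      folds = "loo", seed = 1) {
  nG <- 1020
  es <- matrix(0, nG, 3)
  es[seq(25, by = 50, length.out = 20), 2] <- 0.5
  cfg <- simConfig(nSamples = n, nGenes = nG, nVariants = nG,
                   categoryBlocks = c(ses = 1L), effectSizes = es,
                   missingFraction = 0, noiseSdPhenotype = noiseSd,
                   seed = seed)
  pair <- simLongitudinalPair(cfg, driftSd = driftSd,
                              retention = retention)
  prep <- function(co)
    residualize(normalizeLogCpm(filterGenes(co@expression)),
                covariatePCs(co@covariates@raw))
  e1 <- prep(pair$wave1)
  e2 <- prep(pair$wave2)
  ## train on genes expressed at both waves, so the wave-2 imputation
  ## is defined for every model gene
  common <- intersect(rownames(e1), rownames(e2))
  e1 <- e1[common, ]
  e2 <- e2[common, ]
  ph1 <- phenoValues(pair$wave1@phenotypes)
  y1 <- setNames(ph1$ses_1, rownames(ph1))
  fit <- fitSignature(y1, e1, folds = folds)
  sig1 <- signatureValues(imputeSignatures(list(fit), e1))[, 1]
  sig2 <- signatureValues(imputeSignatures(list(fit), e2))[, 1]
  ph2 <- phenoValues(pair$wave2@phenotypes)
  y2 <- setNames(ph2$ses_1, rownames(ph2))
  out <- validateLongitudinal(y1, y2, sig1, sig2)
  c(out, list(model = fit))
}

#' Beta-approximation study of the permutation pass
#'
#' Runs full (non-adaptive) permutation passes on independent null
#' genes and compares the beta-approximated gene-level p-value with
#' the direct permutation estimate, and the fitted shape2 with the
#' order-statistic expectation (the minimum of m independent uniform
#' p-values is Beta(1, m)).
#'
#' @param nGenes null genes.
#' @param m independent candidate variants per gene.
#' @param nPerm permutations per gene.
#' @param n samples.
#' @param seed study seed.
#' @return list with \code{spearman}, \code{meanShape1},
#'   \code{meanShape2} and the per-gene table.
#' @export
betaApproximationStudy <- function(nGenes = 120, m = 10, nPerm = 10000,
                                   n = 250, seed = 1) {
  cfg <- cisScanConfig(permMin = nPerm, permMax = nPerm)
  set.seed(seed)
  tab <- t(vapply(seq_len(nGenes), function(i) {
    D <- matrix(rbinom(n * m, 2, 0.4), n, m,
                dimnames = list(NULL, paste0("v", seq_len(m))))
    y <- rnorm(n)
    pp <- permutationPass(y, D, cfg, seed = seed + i)
    c(direct = pp$permPDirect, beta = pp$permPBeta,
      shape1 = pp$betaShape1, shape2 = pp$betaShape2)
  }, numeric(4)))
  list(spearman = cor(tab[, "direct"], tab[, "beta"],
                      method = "spearman"),
       meanShape1 = mean(tab[, "shape1"]),
       meanShape2 = mean(tab[, "shape2"]),
       perGene = as.data.frame(tab))
}
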