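## Synthetic cohort generator. The generator is the inverse of the
## models fitted downstream: negative-binomial counts whose log mean
## carries genetic, environmental and interaction effects plus
## technical confounders and cell-composition axes; phenotypes observed
## as latent + Gaussian noise within correlated category blocks.
##
## Reproducibility contract: one master seed; each stage draws from
## seed + a fixed offset so stages are independently reproducible.
.SEED_OFFSETS <- c(genotypes = 1L, truth = 2L, phenotypes = 3L,
                   expression = 4L, wave2 = 5L)

.stageSeed <- function(config, stage)
  (config@seed + .SEED_OFFSETS[[stage]]) %% .Machine$integer.max

#' Create a synthetic-cohort configuration
#'
#' Defaults describe the study design the package is validated against:
#' a cohort of 251 youths, ~2,000 expressed genes, ~5,000 cis variants,
#' 53 phenotype variables in correlated category blocks (including the
#' four blood cell proportions), unit-variance latent traits observed
#' with unit-SD measurement noise (true signal fraction 0.5), and about
#' half of the samples missing per psychosocial variable.
#'
#' When \code{effectSizes} is \code{NULL} a deterministic default is
#' built: roughly a third of genes carry a cis-eQTL effect
#' (\code{betaG} = 0.6 on the natural-log mean), ten "bioactive"
#' variables each drive 20 causal genes (\code{betaE} = 0.5), and 5\% of
#' genes carry a genotype-by-environment interaction
#' (\code{betaGxe} = 0.4) on top of a genetic and environmental main
#' effect.
#'
#' @param nSamples,nGenes,nVariants cohort dimensions.
#' @param mafRange range allele frequencies are drawn from, in (0, 0.5].
#' @param categoryBlocks named integer vector of variables per category.
#' @param effectSizes optional \code{nGenes x 3} matrix (betaG, betaE,
#'   betaGxe); \code{NULL} builds the default pattern above.
#' @param nbDispersion negative-binomial dispersion
#'   (\code{var = mu + dispersion * mu^2}).
#' @param libsizeRange library-size range (log-uniform).
#' @param confounderCount number of Gaussian technical axes.
#' @param noiseSdPhenotype measurement-noise SD on unit-variance latents.
#' @param missingFraction fraction of samples missing per variable.
#' @param blockCor within-block latent correlation.
#' @param seed master seed.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSamples = 60, nGenes = 100, nVariants = 200)
#' cfg
#' @export
simConfig <- function(nSamples = 251, nGenes = 2000, nVariants = 5000,
                      mafRange = c(0.1, 0.5),
                      categoryBlocks = c(ses = 9L, social_relationships = 10L,
                                         emotionality = 10L, asthma = 12L,
                                         biological = 8L,
                                         blood_composition = 4L),
                      effectSizes = NULL, nbDispersion = 0.1,
                      libsizeRange = c(2e6, 8e6), confounderCount = 3,
                      noiseSdPhenotype = 1, missingFraction = 0.5,
                      blockCor = 0.6, seed = 1) {
  categoryBlocks <- setNames(as.integer(categoryBlocks),
                             names(categoryBlocks))
  if (is.null(effectSizes))
    effectSizes <- .defaultEffectSizes(as.integer(nGenes),
                                       categoryBlocks)
  effectSizes <- as.matrix(effectSizes)
  colnames(effectSizes) <- c("betaG", "betaE", "betaGxe")
  new("SimConfig",
      nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
      nVariants = as.integer(nVariants), mafRange = as.numeric(mafRange),
      categoryBlocks = categoryBlocks, effectSizes = effectSizes,
      nbDispersion = as.numeric(nbDispersion),
      libsizeRange = as.numeric(libsizeRange),
      confounderCount = as.integer(confounderCount),
      noiseSdPhenotype = as.numeric(noiseSdPhenotype),
      missingFraction = as.numeric(missingFraction),
      blockCor = as.numeric(blockCor), seed = as.integer(seed))
}

## Variable names: "<category>_<i>"; the blood_composition block, when
## present, is named after the four cell types.
.variableNames <- function(categoryBlocks) {
  unlist(lapply(names(categoryBlocks), function(cat) {
    k <- categoryBlocks[[cat]]
    if (cat == "blood_composition" && k == 4L)
      c("lymphocytes", "neutrophils", "monocytes", "eosinophils")
    else paste0(cat, "_", seq_len(k))
  }), use.names = FALSE)
}

.variableCategories <- function(categoryBlocks)
  setNames(rep(names(categoryBlocks), categoryBlocks),
           .variableNames(categoryBlocks))

## "Bioactive" variables drive expression: up to ten, spread over the
## non-blood blocks (the blood block drives expression through the cell
## proportions instead).
.bioactiveVariables <- function(categoryBlocks, nMax = 10L) {
  cats <- setdiff(names(categoryBlocks), "blood_composition")
  vars <- unlist(lapply(cats, function(cat)
    paste0(cat, "_", seq_len(min(2L, categoryBlocks[[cat]])))),
    use.names = FALSE)
  head(vars, nMax)
}

.defaultEffectSizes <- function(nGenes, categoryBlocks) {
  es <- matrix(0, nGenes, 3,
               dimnames = list(NULL, c("betaG", "betaE", "betaGxe")))
  idx <- seq_len(nGenes)
  sgn <- ifelse(idx %% 2L == 0L, 1, -1)
  eg <- idx %% 3L == 1L
  es[eg, "betaG"] <- 0.6 * sgn[eg]
  nBio <- length(.bioactiveVariables(categoryBlocks))
  env <- which(idx %% 3L == 2L)
  env <- head(env, 20L * nBio)
  es[env, "betaE"] <- 0.5 * sgn[env]
  gxe <- which(idx %% 3L == 0L)
  gxe <- head(gxe, max(1L, round(0.05 * nGenes)))
  es[gxe, "betaG"] <- 0.6 * sgn[gxe]
  es[gxe, "betaE"] <- 0.3 * sgn[gxe]
  es[gxe, "betaGxe"] <- 0.4 * ifelse(gxe %% 4L < 2L, 1, -1)
  es
}

.sampleIds <- function(n) sprintf("S%04d", seq_len(n))
.geneIds   <- function(n) sprintf("G%05d", seq_len(n))
.variantIds <- function(n) sprintf("V%06d", seq_len(n))

## Deterministic genome layout: autosomal genes in contiguous blocks on
## chromosomes 1-22 with 150 kb TSS spacing; the last ~2% of genes sit
## on X/Y to exercise the sex-chromosome filter. Strand alternates.
.geneLayout <- function(config) {
  nG <- config@nGenes
  nSex <- if (nG >= 50L) max(2L, round(0.02 * nG)) else 0L
  nAuto <- nG - nSex
  perChrom <- ceiling(nAuto / 22)
  chrom <- as.character(rep(seq_len(22), each = perChrom)[seq_len(nAuto)])
  within <- (seq_len(nAuto) - 1L) %% perChrom
  tss <- 2e6 + within * 150000
  if (nSex > 0L) {
    nY <- max(1L, nSex %/% 4L)
    chrom <- c(chrom, rep("X", nSex - nY), rep("Y", nY))
    tss <- c(tss, 2e6 + seq_len(nSex) * 150000)
  }
  data.frame(gene_id = .geneIds(nG), chrom = chrom, tss = tss,
             strand = rep_len(c("+", "-"), nG),
             stringsAsFactors = FALSE)
}

## Variants are laid out per gene: each gene owns a block of evenly
## spaced variants within +/-800 kb of its TSS; the one nearest the TSS
## is the gene's assigned cis variant in the TruthSet.
.variantLayout <- function(config) {
  genes <- .geneLayout(config)
  nG <- config@nGenes; nV <- config@nVariants
  base <- nV %/% nG; extra <- nV %% nG
  perGene <- rep(base, nG) + c(rep(1L, extra), rep(0L, nG - extra))
  if (any(perGene == 0L) && nV < nG)
    perGene <- c(rep(1L, nV), rep(0L, nG - nV))
  geneIdx <- rep(seq_len(nG), perGene)
  off <- unlist(lapply(perGene[perGene > 0L], function(k)
    -8e5 + (seq_len(k) - 0.5) * (1.6e6 / k)), use.names = FALSE)
  pos <- pmax(1, round(genes$tss[geneIdx] + off))
  vi <- data.frame(id = .variantIds(length(pos)),
                   chrom = genes$chrom[geneIdx], pos = pos,
                   geneIdx = geneIdx, stringsAsFactors = FALSE)
  assigned <- rep(NA_character_, nG)
  for (g in unique(geneIdx)) {
    rows <- which(vi$geneIdx == g)
    assigned[g] <- vi$id[rows[which.min(abs(vi$pos[rows] - genes$tss[g]))]]
  }
  list(variants = vi[, c("id", "chrom", "pos")], assignedVariant = assigned)
}

#' Simulate genotype dosages
#'
#' Each variant's allele frequency is drawn uniformly from the
#' configured range and per-sample dosages are Binomial(2, f) hard
#' calls; \code{mode = "dosage"} adds truncated Gaussian imputation-like
#' noise so dosages cover [0, 2] continuously. The drawn frequency is
#' kept in \code{rowData} column \code{f}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param mode \code{"hardcall"} (default) or \code{"dosage"}.
#' @param dosageNoiseSd noise SD in dosage mode.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' g <- simGenotypes(simConfig(nSamples = 20, nGenes = 10, nVariants = 30))
#' range(dosages(g))
#' @export
simGenotypes <- function(config, mode = c("hardcall", "dosage"),
                         dosageNoiseSd = 0.1) {
  mode <- match.arg(mode)
  layout <- .variantLayout(config)
  vi <- layout$variants
  nV <- nrow(vi); n <- config@nSamples
  set.seed(.stageSeed(config, "genotypes"))
  f <- runif(nV, config@mafRange[1], config@mafRange[2])
  d <- matrix(rbinom(nV * n, 2L, rep(f, n)), nrow = nV, ncol = n)
  if (mode == "dosage") {
    d <- d + matrix(rnorm(nV * n, sd = dosageNoiseSd), nV, n)
    d[d < 0] <- 0
    d[d > 2] <- 2
  }
  dimnames(d) <- list(vi$id, .sampleIds(n))
  new("GenotypeMatrix", SummarizedExperiment(
    assays = list(dosage = d),
    rowData = DataFrame(chrom = vi$chrom, pos = vi$pos, f = f,
                        row.names = vi$id)))
}

#' Simulate the cohort ground truth
#'
#' Draws the latent (noise-free) trait values, technical confounders and
#' blood cell proportions, and records the per-gene effect sizes and
#' their assigned cis variant and environmental variable.
#'
#' Latent traits are unit variance; variables within a category block
#' load on a shared factor so within-block correlations equal
#' \code{blockCor}. The four blood-composition latents are standardized
#' Dirichlet cell proportions (neutrophil-dominated, as in whole blood).
#' Cell types additionally get dedicated 25-gene expression blocks so
#' cell-composition signatures exist alongside psychosocial ones.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{TruthSet}.
#' @export
simTruth <- function(config) {
  n <- config@nSamples; nG <- config@nGenes
  blocks <- config@categoryBlocks
  vars <- .variableNames(blocks)
  cats <- .variableCategories(blocks)
  set.seed(.stageSeed(config, "truth"))

  ## blood cell proportions: Dirichlet via gamma draws
  alpha <- c(lymphocytes = 6, neutrophils = 11, monocytes = 1.6,
             eosinophils = 0.6)
  gam <- vapply(alpha, function(a) rgamma(n, shape = a), numeric(n))
  cellProps <- gam / rowSums(gam)
  rownames(cellProps) <- .sampleIds(n)

  lat <- matrix(NA_real_, n, length(vars),
                dimnames = list(.sampleIds(n), vars))
  rho <- config@blockCor
  for (cat in names(blocks)) {
    members <- vars[cats[vars] == cat]
    if (cat == "blood_composition" && length(members) == 4L) {
      lat[, members] <- scale(cellProps)
      next
    }
    f <- rnorm(n)
    for (v in members)
      lat[, v] <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)
  }

  nC <- config@confounderCount
  conf <- matrix(rnorm(n * nC), n, nC,
                 dimnames = list(.sampleIds(n),
                                 if (nC) paste0("conf", seq_len(nC))))
  confLoad <- matrix(0, nG, nC,
                     dimnames = list(.geneIds(nG), colnames(conf)))
  if (nC)
    for (j in seq_len(nC)) {
      hit <- sample.int(nG, size = max(1L, round(0.2 * nG)))
      confLoad[hit, j] <- rnorm(length(hit), sd = 0.3)
    }

  ## dedicated cell-type gene blocks (disjoint from env-causal genes)
  cellLoad <- matrix(0, nG, 4L,
                     dimnames = list(.geneIds(nG), names(alpha)))
  free <- which(config@effectSizes[, "betaE"] == 0 &
                config@effectSizes[, "betaGxe"] == 0)
  perType <- min(25L, max(1L, length(free) %/% 4L))
  for (j in seq_len(4L)) {
    take <- free[seq_len(min(perType, length(free)))]
    free <- setdiff(free, take)
    cellLoad[take, j] <- 0.5
  }

  bio <- .bioactiveVariables(blocks)
  assignedVariable <- rep(NA_character_, nG)
  active <- which(config@effectSizes[, "betaE"] != 0 |
                  config@effectSizes[, "betaGxe"] != 0)
  if (length(active) && length(bio))
    assignedVariable[active] <-
      bio[((seq_along(active) - 1L) %% length(bio)) + 1L]

  baseLogMean <- runif(nG, log(2), log(500))

  new("TruthSet",
      latentTraits = lat,
      betaG = setNames(config@effectSizes[, "betaG"], .geneIds(nG)),
      betaE = setNames(config@effectSizes[, "betaE"], .geneIds(nG)),
      betaGxe = setNames(config@effectSizes[, "betaGxe"], .geneIds(nG)),
      assignedVariant = .variantLayout(config)$assignedVariant,
      assignedVariable = assignedVariable,
      confounderLoadings = confLoad, confounders = conf,
      cellLoadings = cellLoad, cellProps = cellProps,
      baseLogMean = setNames(baseLogMean, .geneIds(nG)))
}

#' Simulate measured phenotypes
#'
#' Observed value = latent + Gaussian measurement noise, with a
#' configurable fraction of samples set missing per variable (matching
#' studies where deep phenotyping covers only part of the cohort).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth the matching \linkS4class{TruthSet}.
#' @return a \linkS4class{PhenotypeTable}.
#' @export
simPhenotypes <- function(config, truth) {
  lat <- latentTraits(truth)
  if (!nrow(lat)) stop("truth has no latent traits")
  n <- nrow(lat)
  set.seed(.stageSeed(config, "phenotypes"))
  obs <- lat + matrix(rnorm(length(lat), sd = config@noiseSdPhenotype),
                      n, ncol(lat))
  if (config@missingFraction > 0) {
    nMiss <- round(config@missingFraction * n)
    for (j in seq_len(ncol(obs)))
      obs[sample.int(n, nMiss), j] <- NA_real_
  }
  df <- as.data.frame(obs)
  rownames(df) <- rownames(lat)
  new("PhenotypeTable", data = df,
      categories = .variableCategories(config@categoryBlocks))
}

#' Simulate negative-binomial expression counts
#'
#' Counts are negative binomial with
#' \code{log mu = base + betaG * dosage + betaE * latent +
#' betaGxe * dosage * latent + confounders + cell composition +
#' log(libsize share)}; the generative inverse of the interaction model
#' fitted downstream. Effects are on the natural-log scale, so
#' \code{betaG = log(2)} doubles the mean per alternate allele.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param genotypes the matching \linkS4class{GenotypeMatrix}.
#' @param truth the matching \linkS4class{TruthSet}.
#' @return an \linkS4class{ExpressionMatrix} with a \code{counts} assay.
#' @export
simExpression <- function(config, genotypes, truth) {
  n <- config@nSamples; nG <- config@nGenes
  genes <- .geneLayout(config)
  d <- dosages(genotypes)
  lat <- latentTraits(truth)
  set.seed(.stageSeed(config, "expression"))
  libsize <- exp(runif(n, log(config@libsizeRange[1]),
                       log(config@libsizeRange[2])))

  eta <- matrix(truth@baseLogMean, nG, n) # genes x samples
  hasG <- which(truth@betaG != 0 | truth@betaGxe != 0)
  for (g in hasG) {
    dg <- d[truth@assignedVariant[g], ]
    eta[g, ] <- eta[g, ] + truth@betaG[g] * dg
    if (truth@betaGxe[g] != 0 || truth@betaE[g] != 0) {
      ev <- lat[, truth@assignedVariable[g]]
      eta[g, ] <- eta[g, ] + truth@betaE[g] * ev +
        truth@betaGxe[g] * dg * ev
    }
  }
  hasEonly <- which(truth@betaE != 0 & truth@betaG == 0 &
                    truth@betaGxe == 0)
  for (g in hasEonly)
    eta[g, ] <- eta[g, ] + truth@betaE[g] * lat[, truth@assignedVariable[g]]
  if (ncol(truth@confounders))
    eta <- eta + truth@confounderLoadings %*% t(truth@confounders)
  eta <- eta + truth@cellLoadings %*% t(scale(truth@cellProps))
  eta <- eta + matrix(log(libsize / 1e6), nG, n, byrow = TRUE)

  if (any(!is.finite(eta))) {
    bad <- which(!is.finite(eta), arr.ind = TRUE)[1, ]
    stop(sprintf("nonfinite expression log-mean for gene %s, sample %s",
                 .geneIds(nG)[bad[1]], .sampleIds(n)[bad[2]]))
  }
  mu <- exp(eta)
  cts <- matrix(rnbinom(nG * n, size = 1 / config@nbDispersion, mu = mu),
                nG, n, dimnames = list(genes$gene_id, .sampleIds(n)))
  storage.mode(cts) <- "integer" 
  se <- SummarizedExperiment(
    assays = list(counts = cts),
    rowData = DataFrame(chrom = genes$chrom, tss = genes$tss,
                        strand = genes$strand, row.names = genes$gene_id),
    colData = DataFrame(libsize = libsize, row.names = .sampleIds(n)))
  new("ExpressionMatrix", se)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running \code{\link{simGenotypes}},
#' \code{\link{simTruth}}, \code{\link{simPhenotypes}} and
#' \code{\link{simExpression}} under the configuration's master seed and
#' bundling the results with the technical covariates.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param genotypeMode passed to \code{\link{simGenotypes}}.
#' @return a \linkS4class{SimCohort}.
#' @examples
#' co <- simCohort(simConfig(nSamples = 40, nGenes = 60, nVariants = 120))
#' co
#' @export
simCohort <- function(config, genotypeMode = "hardcall") {
  genotypes <- simGenotypes(config, mode = genotypeMode)
  truth <- simTruth(config)
  phenotypes <- simPhenotypes(config, truth)
  expression <- simExpression(config, genotypes, truth)
  covariates <- new("CovariateSet",
                    raw = as.data.frame(truth@confounders),
                    pcs = matrix(numeric(), nrow = config@nSamples,
                                 ncol = 0),
                    varianceExplained = numeric())
  new("SimCohort", genotypes = genotypes, expression = expression,
      phenotypes = phenotypes, covariates = covariates, truth = truth,
      config = config)
}

#' Simulate a two-wave longitudinal cohort pair
#'
#' Wave-2 latent traits equal wave-1 latents plus per-sample Gaussian
#' drift; genotypes are identical across waves; expression, phenotypes
#' and technical covariates are regenerated from the wave-2 latents for
#' the retained subset of samples. Used to validate that imputed
#' signature changes track observed phenotype changes.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param driftSd SD of the per-sample latent drift.
#' @param retention fraction of wave-1 samples present at wave 2.
#' @param driftVariables variables the drift applies to (default all).
#' @return a list with elements \code{wave1} and \code{wave2} (both
#'   \linkS4class{SimCohort}) and \code{drift}, the true latent change
#'   matrix for the wave-2 samples.
#' @export
simLongitudinalPair <- function(config, driftSd = 1, retention = 0.4,
                                driftVariables = NULL) {
  wave1 <- simCohort(config)
  truth1 <- wave1@truth
  n <- config@nSamples
  set.seed(.stageSeed(config, "wave2"))
  keep <- sort(sample.int(n, size = max(5L, round(retention * n))))
  lat1 <- latentTraits(truth1)
  drift <- matrix(0, n, ncol(lat1), dimnames = dimnames(lat1))
  targetVars <- if (is.null(driftVariables)) colnames(lat1)
                else driftVariables
  drift[, targetVars] <- rnorm(n * length(targetVars), sd = driftSd)
  lat2 <- lat1 + drift

  truth2 <- truth1
  truth2@latentTraits <- lat2
  ## wave-2 technical axes are fresh draws (new batches, new RIN)
  truth2@confounders <- matrix(
    rnorm(length(truth1@confounders)),
    nrow(truth1@confounders), ncol(truth1@confounders),
    dimnames = dimnames(truth1@confounders))

  cfg2 <- config
  cfg2@seed <- .stageSeed(config, "wave2")
  pheno2 <- simPhenotypes(cfg2, truth2)
  expr2 <- simExpression(cfg2, wave1@genotypes, truth2)

  subsetCohort <- function(co, idx) {
    ids <- .sampleIds(n)[idx]
    new("SimCohort",
        genotypes = new("GenotypeMatrix", co@genotypes[, ids]),
        expression = new("ExpressionMatrix", co@expression[, ids]),
        phenotypes = new("PhenotypeTable",
                         data = phenoValues(co@phenotypes)[ids, ,
                                                           drop = FALSE],
                         categories = phenoCategories(co@phenotypes)),
        covariates = new("CovariateSet",
                         raw = co@covariates@raw[ids, , drop = FALSE],
                         pcs = matrix(numeric(), length(ids), 0),
                         varianceExplained = numeric()),
        truth = co@truth, config = co@config)
  }
  wave2full <- new("SimCohort", genotypes = wave1@genotypes,
                   expression = expr2, phenotypes = pheno2,
                   covariates = new("CovariateSet",
                                    raw = as.data.frame(truth2@confounders),
                                    pcs = matrix(numeric(), n, 0),
                                    varianceExplained = numeric()),
                   truth = truth2, config = cfg2)
  list(wave1 = wave1, wave2 = subsetCohort(wave2full, keep),
       drift = drift[keep, , drop = FALSE])
}
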