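test_that("invalid configurations are rejected", {
  expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(simConfig(mafRange = c(0.1, 0.6)), "mafRange")
  expect_error(simConfig(nbDispersion = 0), "nbDispersion")
  expect_error(simConfig(missingFraction = 1), "missingFraction")
})

test_that("genotype generation is deterministic and marginally correct", {
  cfg <- simConfig(nSamples = 10000, nGenes = 5, nVariants = 10,
                   mafRange = c(0.5, 0.5), seed = 7)
  g1 <- simGenotypes(cfg)
  g2 <- simGenotypes(cfg)
  expect_identical(dosages(g1), dosages(g2))
  expect_true(all(dosages(g1) %in% 0:2))
  ## f = 0.5 at n = 10,000: mean dosage within CLT bounds
  expect_true(all(abs(rowMeans(dosages(g1)) - 1) < 0.02))

  ## empirical allele frequency within 3 binomial SDs of the drawn f
  cfg2 <- tinyConfig()
  g <- simGenotypes(cfg2)
  f <- variantInfo(g)$f
  n <- cfg2@nSamples
  fhat <- rowMeans(dosages(g)) / 2
  sdBound <- 3 * sqrt(f * (1 - f) / (2 * n))
  expect_gt(mean(abs(fhat - f) <= sdBound), 0.99)
})

test_that("dosage mode stays inside [0, 2]", {
  cfg <- tinyConfig()
  g <- simGenotypes(cfg, mode = "dosage")
  d <- dosages(g)
  expect_true(all(d >= 0 & d <= 2))
  expect_gt(mean(d != round(d)), 0.5)
})

test_that("phenotypes are latent plus noise with block correlation", {
  ## noiseless limit: observed equals latent exactly
  cfg0 <- tinyConfig(noiseSdPhenotype = 0, missingFraction = 0)
  tr0 <- simTruth(cfg0)
  ph0 <- simPhenotypes(cfg0, tr0)
  expect_equal(as.matrix(phenoValues(ph0)), latentTraits(tr0),
               ignore_attr = TRUE)

  ## within-block latent correlations exceed between-block ones
  cfg <- simConfig(nSamples = 2000, nGenes = 30, nVariants = 60,
                   blockCor = 0.6, seed = 2)
  tr <- simTruth(cfg)
  lat <- latentTraits(tr)
  cats <- phenoCategories(simPhenotypes(cfg, tr))
  rr <- cor(lat)
  same <- outer(cats, cats, "==")
  diag(same) <- NA
  expect_gt(mean(rr[same & !is.na(same)]), mean(rr[!same & !is.na(same)]))
  ## and match the configured block correlation
  ses <- lat[, cats == "ses"]
  offdiag <- cor(ses)[upper.tri(cor(ses))]
  expect_equal(mean(offdiag), 0.6, tolerance = 0.1)
})

test_that("measurement noise attenuates observed vs latent r2 to ~0.5", {
  cfg <- simConfig(nSamples = 5000, nGenes = 30, nVariants = 60,
                   noiseSdPhenotype = 1, missingFraction = 0, seed = 4)
  tr <- simTruth(cfg)
  ph <- simPhenotypes(cfg, tr)
  v <- "emotionality_3"
  r2 <- cor(phenoValues(ph)[[v]], latentTraits(tr)[, v])^2
  expect_equal(r2, 0.5, tolerance = 0.05)
})

test_that("missingness fraction is honoured", {
  cfg <- tinyConfig(missingFraction = 0.4)
  ph <- simPhenotypes(cfg, simTruth(cfg))
  miss <- colMeans(is.na(phenoValues(ph)))
  expect_true(all(abs(miss - 0.4) < 0.02))
})

test_that("expression counts follow the configured NB law", {
  ## Poisson limit: all betas 0, dispersion -> 0, var/mean ~ 1
  cfg <- simConfig(nSamples = 5000, nGenes = 40, nVariants = 80,
                   effectSizes = matrix(0, 40, 3), nbDispersion = 1e-8,
                   confounderCount = 0, libsizeRange = c(4e6, 4e6),
                   seed = 9)
  tr <- simTruth(cfg)
  tr@cellLoadings[] <- 0
  cts <- counts(simExpression(cfg, simGenotypes(cfg), tr))
  vmr <- apply(cts, 1, var) / rowMeans(cts)
  expect_true(all(abs(vmr - 1) < 0.15))

  ## NB mean-variance relation var = mu + disp * mu^2
  cfg2 <- cfg
  cfg2@nbDispersion <- 0.2
  cts2 <- counts(simExpression(cfg2, simGenotypes(cfg2), tr))
  mu <- rowMeans(cts2)
  v <- apply(cts2, 1, var)
  expected <- mu + 0.2 * mu^2
  expect_lt(median(abs(v / expected - 1)), 0.15)
})

test_that("a log(2) dosage effect quadruples mean counts for dosage 2", {
  nG <- 10
  es <- matrix(0, nG, 3)
  es[, 1] <- log(2)
  cfg <- simConfig(nSamples = 8000, nGenes = nG, nVariants = nG,
                   effectSizes = es, confounderCount = 0,
                   libsizeRange = c(4e6, 4e6), mafRange = c(0.5, 0.5),
                   seed = 12)
  tr <- simTruth(cfg)
  tr@cellLoadings[] <- 0
  g <- simGenotypes(cfg)
  cts <- counts(simExpression(cfg, g, tr))
  gene <- which.max(tr@baseLogMean)[1]
  d <- dosages(g)[tr@assignedVariant[gene], ]
  ratio <- mean(cts[gene, d == 2]) / mean(cts[gene, d == 0])
  expect_equal(ratio, 4, tolerance = 0.25)
})

test_that("expression generation is deterministic for a fixed seed", {
  cfg <- tinyConfig()
  g <- simGenotypes(cfg); tr <- simTruth(cfg)
  expect_identical(counts(simExpression(cfg, g, tr)),
                   counts(simExpression(cfg, g, tr)))
})

test_that("the full cohort is byte-identical after serialization", {
  co1 <- simCohort(tinyConfig())
  co2 <- simCohort(tinyConfig())
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))
})

test_that("TruthSet validity requires a variant for interaction genes", {
  tr <- simTruth(tinyConfig())
  tr2 <- tr
  expect_error({
    tr2@assignedVariant[which(tr2@betaGxe != 0)[1]] <- NA_character_
    validObject(tr2)
  }, "assigned cis variant")
})

test_that("truth round-trips through JSON serialization", {
  tr <- simTruth(tinyConfig())
  path <- withr::local_tempfile(fileext = ".json")
  writeTruth(tr, path)
  back <- readTruth(path)
  expect_equal(latentTraits(back), latentTraits(tr))
  expect_identical(back@assignedVariant, tr@assignedVariant)
  expect_equal(back@betaGxe, tr@betaGxe)
  expect_equal(back@cellProps, tr@cellProps)
})

test_that("longitudinal pairs drift as configured", {
  cfg <- tinyConfig()
  ## zero drift: wave-2 latents equal wave-1 latents
  p0 <- simLongitudinalPair(cfg, driftSd = 0)
  expect_equal(latentTraits(p0$wave2@truth), latentTraits(p0$wave1@truth))

  ## drift restricted to one variable leaves the others untouched
  p1 <- simLongitudinalPair(cfg, driftSd = 1, driftVariables = "ses_1")
  delta <- latentTraits(p1$wave2@truth) - latentTraits(p1$wave1@truth)
  expect_true(all(delta[, colnames(delta) != "ses_1"] == 0))
  expect_gt(sd(delta[, "ses_1"]), 0.5)

  ## wave-2 samples are a subset of wave 1
  expect_true(all(colnames(p1$wave2@expression) %in%
                  colnames(p1$wave1@expression)))
})

test_that("observed deltas track true deltas in the drift scenario", {
  cfg <- simConfig(nSamples = 250, nGenes = 40, nVariants = 80,
                   noiseSdPhenotype = 0.3, missingFraction = 0,
                   seed = 21)
  pair <- simLongitudinalPair(cfg, driftSd = 1, retention = 1)
  v <- "ses_1"
  ids <- rownames(phenoValues(pair$wave2@phenotypes))
  obsDelta <- phenoValues(pair$wave2@phenotypes)[ids, v] -
    phenoValues(pair$wave1@phenotypes)[ids, v]
  trueDelta <- pair$drift[ids, v]
  expect_gte(cor(obsDelta, trueDelta, method = "spearman"), 0.8)
})
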