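test_that("the inverse normal transform matches the Blom formula", {
  out <- inverseNormalTransform(c(5, 1, 9))
  blom <- qnorm((c(2, 1, 3) - 3 / 8) / (3 + 1 / 4))
  expect_equal(out, blom, tolerance = 1e-12)
  expect_equal(out, c(0, -0.8694, 0.8694), tolerance = 1e-3)
})

test_that("the transform is rank-invariant, calibrated and guards ties", {
  set.seed(71)
  x <- rnorm(250)
  expect_identical(inverseNormalTransform(x),
                   inverseNormalTransform(exp(3 * x))) # monotone map
  z <- inverseNormalTransform(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_true(sd(z) >= 0.9 && sd(z) <= 1.0)
  ## ties share the average rank
  zt <- inverseNormalTransform(c(1, 2, 2, 3))
  expect_equal(zt[2], zt[3])
  ## NAs pass through
  zna <- inverseNormalTransform(c(1, NA, 2, 3))
  expect_true(is.na(zna[2]) && !anyNA(zna[-2]))
  expect_error(inverseNormalTransform(rep(1, 10)), "identical")
  expect_error(inverseNormalTransform(c(1, 2)), "3 finite")
})

test_that("the interaction fit matches explicit least squares", {
  set.seed(72)
  n <- 120
  d <- rbinom(n, 2, 0.3)
  e <- rnorm(n)
  y <- 0.5 + 0.3 * d - 0.2 * e + 0.4 * d * e + rnorm(n)
  rec <- fitInteraction(y, d, e)
  ## independent oracle: normal equations by hand
  X <- cbind(1, d, e, d * e)
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, y)
  res <- y - X %*% beta
  sig2 <- sum(res^2) / (n - 4)
  se <- sqrt(diag(XtXi) * sig2)
  tv <- beta / se
  pv <- 2 * pt(-abs(tv), n - 4)
  expect_equal(unlist(rec[paste0("b_", sigQTL:::.GXE_TERMS)]),
               as.numeric(beta), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unlist(rec[paste0("se_", sigQTL:::.GXE_TERMS)]),
               as.numeric(se), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unlist(rec[paste0("p_", sigQTL:::.GXE_TERMS)]),
               as.numeric(pv), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(fitInteraction(y, d, rep(0, n)), "rank deficient")
})

test_that("the batched permutation fitter agrees with the per-fit route", {
  set.seed(73)
  n <- 90
  e <- inverseNormalTransform(rnorm(n))
  y <- rnorm(n)
  D <- vapply(1:6, function(i) rbinom(n, 2, 0.4), numeric(n))
  batch <- sigQTL:::.interactionScan(y, e, D, full = TRUE)
  for (j in 1:6) {
    rec <- fitInteraction(y, D[, j], e)
    expect_equal(batch$p[j], rec$p_interaction, tolerance = 1e-8)
    expect_equal(batch$b[j], rec$b_interaction, tolerance = 1e-8)
    expect_equal(batch$se[j], rec$se_interaction, tolerance = 1e-8)
  }
})

test_that("orthogonal covariates leave the interaction estimate unchanged", {
  set.seed(74)
  n <- 150
  d <- rbinom(n, 2, 0.3)
  e <- rnorm(n)
  y <- 0.2 * d + 0.1 * e + 0.3 * d * e + rnorm(n)
  raw <- matrix(rnorm(n * 3), n, 3)
  ## orthogonalize the covariates against every model term and y
  cov <- qr.resid(qr(cbind(1, d, e, d * e, y)), raw)
  a <- fitInteraction(y, d, e)
  b <- fitInteraction(y, d, e, covariates = cov)
  expect_equal(b$b_interaction, a$b_interaction, tolerance = 1e-8)
})

test_that("cell-composition-style covariates shift estimates modestly", {
  set.seed(75)
  n <- 200
  d <- rbinom(n, 2, 0.3)
  e <- rnorm(n)
  y <- 0.4 * d * e + 0.3 * d + rnorm(n)
  cov <- matrix(rnorm(n * 4), n, 4) # zero true effect
  a <- fitInteraction(y, d, e)
  b <- fitInteraction(y, d, e, covariates = cov)
  expect_lt(abs(b$b_interaction - a$b_interaction),
            2 * a$se_interaction)
})

test_that("the empirical correction follows the pseudocount formula", {
  nullStore <- new("NullStore", signature = "sig",
                   nullP = seq(0.002, 1, length.out = 999),
                   nNull = 999L, seed = 1L)
  rec <- data.frame(gene = c("g1", "g2"), variant = c("v1", "v2"),
                    p_interaction = c(0.001, 0.5),
                    signature = "sig")
  out <- correctAndQvalue(rec, nullStore)
  ## below every null value: (1 + 0) / (1 + 999)
  expect_equal(out$p_interaction_permcorrected[1], 1 / 1000)

  ## hand count: 5 of 999 null values <= 0.001 -> (5 + 1)/(999 + 1)
  ns2 <- new("NullStore", signature = "sig",
             nullP = c(rep(0.0005, 5), seq(0.1, 1, length.out = 994)),
             nNull = 999L, seed = 1L)
  out2 <- correctAndQvalue(rec, ns2)
  expect_equal(out2$p_interaction_permcorrected[1], 6 / 1000)

  expect_error(correctAndQvalue(rec, new("NullStore", signature = "other",
                                         nullP = 0.5, nNull = 1L,
                                         seed = 1L)), "does not match")
})

test_that("corrected p-values are monotone and q-values BH at pi0 = 1", {
  set.seed(76)
  nullStore <- new("NullStore", signature = "sig", nullP = runif(5000),
                   nNull = 5000L, seed = 1L)
  rec <- data.frame(gene = paste0("g", 1:20), variant = paste0("v", 1:20),
                    p_interaction = sort(runif(20)), signature = "sig")
  out <- correctAndQvalue(rec, nullStore, pi0 = 1)
  expect_true(all(diff(out$p_interaction_permcorrected) >= 0))
  expect_equal(out$q_interaction_permcorrected,
               p.adjust(out$p_interaction_permcorrected, "BH"),
               tolerance = 1e-12)
})

test_that("the permutation null store is deterministic bookkeeping", {
  co <- tinyCohort()
  expr <- tinyExpr()
  leads <- data.frame(gene = rownames(expr)[1:5],
                      bestVariant = variantInfo(co@genotypes)$id[1:5])
  env <- setNames(rnorm(ncol(expr)), colnames(expr))
  ns1 <- buildPermutationNull(expr, co@genotypes, leads, env,
                              nNull = 500, seed = 3)
  ns2 <- buildPermutationNull(expr, co@genotypes, leads, env,
                              nNull = 500, seed = 3)
  expect_identical(nullValues(ns1), nullValues(ns2))
  expect_equal(ns1@nNull, 500) # 5 leads x 100 rounds, truncated exactly
  expect_true(all(nullValues(ns1) >= 0 & nullValues(ns1) <= 1))
  expect_warning(buildPermutationNull(expr, co@genotypes, leads, env,
                                      nNull = 20, seed = 3), "10x")
})

test_that("enrichment reproduces hand odds ratios and exact p-values", {
  universe <- paste0("g", 1:200)
  ## table (20, 30, 10, 140): OR = 20*140 / (30*10) = 9.33
  setA <- universe[1:50]
  setB <- universe[c(1:20, 51:60)]
  out <- replicationEnrichment(setA, setB, universe)
  expect_equal(out$oddsRatio, 20 * 140 / (30 * 10), tolerance = 1e-12)
  expect_equal(unname(out$table[1, 1]), 20)
  expect_false(out$continuityCorrected)
  ## p agrees with the established implementation
  expect_equal(out$p,
               fisher.test(matrix(c(20, 30, 10, 140), 2,
                                  byrow = TRUE))$p.value,
               tolerance = 1e-10)
  ## an empty cell triggers the continuity correction
  out0 <- replicationEnrichment(universe[1:5], universe[1:5], universe)
  expect_true(out0$continuityCorrected)
  expect_error(replicationEnrichment("x", "y", character()), "empty")
  expect_error(replicationEnrichment("zz", universe[1], universe),
               "subsets")
})

test_that("random half-universe splits are not enriched", {
  set.seed(77)
  universe <- paste0("g", 1:400)
  reps <- replicate(20, {
    a <- sample(universe, 200)
    b <- sample(universe, 200)
    out <- replicationEnrichment(a, b, universe)
    c(out$oddsRatio, out$p)
  })
  expect_equal(median(reps[1, ]), 1, tolerance = 0.25)
  expect_gt(mean(reps[2, ] > 0.05), 0.7)
})

test_that("effect concordance joins records and handles sign flips", {
  rec <- data.frame(gene = paste0("g", 1:10), variant = paste0("v", 1:10),
                    signature = "s",
                    b_interaction = rnorm(10),
                    se_interaction = runif(10, 0.5, 1))
  out <- effectConcordance(rec, rec)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$nPairs, 10)
  flip <- rec
  flip$b_interaction <- -flip$b_interaction
  expect_equal(effectConcordance(rec, flip)$r, -1, tolerance = 1e-12)
  expect_error(effectConcordance(rec[1:2, ], rec[1:2, ]), "fewer than 3")
})

test_that("TWAS overlap is plain set arithmetic", {
  rec <- data.frame(gene = paste0("g", 1:5), variant = paste0("v", 1:5),
                    signature = "ses",
                    q_signature = c(0.01, 0.5, 0.02, 0.9, 0.05),
                    q_interaction_permcorrected =
                      c(0.05, 0.08, 0.09, 0.5, 0.9))
  twas <- data.frame(gene = c("g2", "g3", "g9"), trait = "asthma",
                     significant = TRUE)
  out <- twasOverlap(rec, twas)
  gxe <- out[out$set == "gxe", ]
  expect_equal(gxe$nOverlap, 2) # {g1,g2,g3} meets {g2,g3,g9} in g2,g3
  expect_equal(gxe$genes, "g2,g3")
  marg <- out[out$set == "marginal", ]
  expect_equal(marg$nOverlap, 1) # {g1,g3,g5} meets the TWAS set in g3

  ## TWAS set = all genes: overlap equals the significant sets
  twasAll <- data.frame(gene = paste0("g", 1:5), trait = "asthma",
                        significant = TRUE)
  outAll <- twasOverlap(rec, twasAll)
  expect_equal(outAll$nOverlap[outAll$set == "gxe"],
               outAll$nSet[outAll$set == "gxe"])

  ## an empty TWAS table yields empty overlaps without error
  out0 <- twasOverlap(rec, twas[0, ])
  expect_equal(nrow(out0), 0)
  expect_error(twasOverlap(rec, data.frame(gene = "g1")), "missing")
})
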