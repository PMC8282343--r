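test_that("candidate selection applies the window and MAF rules", {
  ann <- data.frame(gene_id = "g1", chrom = "1", tss = 5e6,
                    strand = "+")
  n <- 10
  d <- rbind(v_in = rep(1, n), v_out = rep(1, n),
             v_mono = rep(0, n),
             v_half = c(0, 0, 0, 1, 1, 1, 1, 2, 2, 2))
  d["v_in", 1:5] <- 0 # give the kept variants some variance
  gt <- genotypesFromMatrix(d, pos = c(6e6, 6e6 + 1, 6e6, 5.5e6))
  cfg <- cisScanConfig()
  cand <- cisCandidates("g1", ann, gt, cfg)
  expect_true("v_in" %in% cand$id)      # |pos - tss| = 1e6, inclusive
  expect_false("v_out" %in% cand$id)    # one bp past the window
  expect_false("v_mono" %in% cand$id)   # MAF 0 is not > 0.1
  ## dosages (0,0,0,1,1,1,1,2,2,2): m = 0.5, MAF 0.5 -> included
  expect_true("v_half" %in% cand$id)
  expect_equal(cand$maf[cand$id == "v_half"], 0.5)
  expect_error(cisCandidates("nope", ann, gt, cfg), "absent")
})

test_that("chromosome dialects are reconciled", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", tss = 5e6,
                    strand = "+")
  d <- matrix(rep(c(0, 1, 2, 1), 5), nrow = 1,
              dimnames = list("v1", NULL))
  gt <- genotypesFromMatrix(d, chrom = "1", pos = 5e6)
  cand <- cisCandidates("g1", ann, gt, cisScanConfig())
  expect_equal(cand$id, "v1")
})

test_that("the nominal scan matches an independent least-squares oracle", {
  set.seed(61)
  n <- 50
  D <- matrix(rbinom(n * 8, 2, 0.4), n, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  y <- rnorm(n)
  scan <- nominalScan(y, D)
  for (j in 1:8) {
    fit <- summary(lm(y ~ D[, j]))$coefficients
    expect_equal(scan$slope[j], fit[2, 1], tolerance = 1e-8)
    expect_equal(scan$se[j], fit[2, 2], tolerance = 1e-8)
    expect_equal(scan$p[j], fit[2, 4], tolerance = 1e-8)
  }
})

test_that("the nominal scan handles exact and degenerate relations", {
  n <- 40
  d <- rep(c(0, 1, 2, 1), 10)
  scan <- nominalScan(2 * d, matrix(d, ncol = 1))
  expect_equal(scan$slope[1], 2, tolerance = 1e-12)
  expect_lt(scan$p[1], 1e-12)
  ## orthogonal expression: slope 0 within numerical error
  y <- rnorm(n)
  y <- qr.resid(qr(cbind(1, d)), y)
  expect_lt(abs(nominalScan(y, matrix(d, ncol = 1))$slope[1]), 1e-10)
  ## constant dosage is skipped, not an error
  scan2 <- nominalScan(y, cbind(v1 = d, v2 = rep(1, n)))
  expect_true(scan2$skipped[2])
  expect_false(scan2$skipped[1])
  expect_error(nominalScan(rnorm(5), matrix(rbinom(5, 2, 0.5))), "10")
})

test_that("direct permutation p follows the (1 + hits)/(1 + P) formula", {
  set.seed(62)
  n <- 60
  d <- rbinom(n, 2, 0.4)
  y <- d + rnorm(n, sd = 0.05) # overwhelming signal: no permutation wins
  cfg <- cisScanConfig(permMin = 1000, permMax = 1000)
  pp <- permutationPass(y, matrix(d, ncol = 1,
                                  dimnames = list(NULL, "v1")), cfg)
  expect_equal(pp$permPDirect, 1 / 1001)
  expect_equal(pp$nPerm, 1000)
})

test_that("adaptive permutation stops early for clearly null genes", {
  set.seed(63)
  n <- 80
  D <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  cfg <- cisScanConfig(permMin = 500, permMax = 10000,
                       adaptiveStopHits = 100)
  pp <- permutationPass(rnorm(n), D, cfg)
  expect_equal(pp$nPerm, 500) # a null gene accumulates hits immediately
  expect_gte(sum(pp$permMinima <= pp$nominalP), 100)
})

test_that("a single null variant yields the uniform Beta(1,1) law", {
  set.seed(64)
  n <- 100
  d <- rbinom(n, 2, 0.5)
  cfg <- cisScanConfig(permMin = 10000, permMax = 10000)
  pp <- permutationPass(rnorm(n), matrix(d, ncol = 1,
                                         dimnames = list(NULL, "v1")),
                        cfg)
  ## the minimum over one uniform p-value is uniform: shapes ~ (1, 1)
  expect_equal(pp$betaShape1, 1, tolerance = 0.1)
  expect_equal(pp$betaShape2, 1, tolerance = 0.1)
  expect_equal(pp$permPBeta, pp$nominalP, tolerance = 0.02)
})

test_that("m independent null variants fit a Beta(1, m) null", {
  set.seed(65)
  n <- 150
  m <- 10
  D <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(NULL, paste0("v", 1:m)))
  cfg <- cisScanConfig(permMin = 10000, permMax = 10000)
  pp <- permutationPass(rnorm(n), D, cfg)
  expect_equal(pp$betaShape2, m, tolerance = 0.2 * m)
  expect_equal(pp$betaShape1, 1, tolerance = 0.25)
})

test_that("gene-level FDR with pi0 = 1 reproduces hand BH", {
  set.seed(66)
  rec <- data.frame(gene = paste0("g", 1:1000),
                    permPBeta = c(rep(0.001, 10), runif(990)))
  out <- geneFdr(rec, fdrLevel = 0.10, pi0 = 1)
  bh <- p.adjust(rec$permPBeta, "BH")
  expect_equal(out$qvalue, bh, tolerance = 1e-12)
  expect_true(all(out$eGene[1:10]))
  expect_error(geneFdr(data.frame(permPBeta = c(0.5, 2))), "0, 1")
})

test_that("mapping is invariant to variant input order", {
  co <- tinyCohort()
  expr <- tinyExpr()[1:12, ]
  cfg <- cisScanConfig(permMin = 200, permMax = 200)
  r1 <- mapCisEqtl(expr, co@genotypes, cfg)
  set.seed(99)
  shuffled <- co@genotypes[sample(nrow(co@genotypes)), ]
  r2 <- mapCisEqtl(expr, shuffled, cfg)
  expect_equal(r1[order(r1$gene), ], r2[order(r2$gene), ],
               ignore_attr = TRUE)
})

test_that("permutation null nominal p-values are uniform", {
  set.seed(67)
  n <- 120
  d <- rbinom(n, 2, 0.4)
  ## permuted-expression null: nominal p over 10,000 draws is U(0,1)
  p <- vapply(seq_len(10000), function(i)
    nominalScan(rnorm(n), matrix(d, ncol = 1))$p[1], numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("expression-PC optimization recovers a masking confounder", {
  set.seed(68)
  n <- 120; nGenes <- 40
  d <- matrix(rbinom(nGenes * n, 2, 0.4), nGenes, n,
              dimnames = list(paste0("v", 1:nGenes),
                              sprintf("s%03d", 1:n)))
  conf <- rnorm(n, sd = 3) # one strong expression-wide axis
  r <- matrix(rnorm(nGenes * n, sd = 1), nGenes, n,
              dimnames = list(paste0("g", 1:nGenes), colnames(d)))
  r <- r + 0.45 * d + outer(rep(1, nGenes), conf)
  e <- withResid(r)
  rowData(e)$tss <- rep(5e6, nGenes)
  gt <- genotypesFromMatrix(d, pos = rep(5e6, nGenes))
  ## restrict each gene to its own variant via a tiny window
  cfg <- cisScanConfig(windowBp = 1, permMin = 200, permMax = 200)
  vvi <- variantInfo(gt)
  ## give gene i and variant i matching positions
  rowData(e)$tss <- seq(1e6, by = 2000, length.out = nGenes)
  gt <- genotypesFromMatrix(d, pos = seq(1e6, by = 2000,
                                         length.out = nGenes))
  out <- optimizeExpressionPCs(e, gt, cfg, pcGrid = c(0, 1))
  expect_gt(out$eGeneCounts[["1"]], out$eGeneCounts[["0"]])
  expect_equal(out$chosenK, 1)
  ## a grid of {0} trivially chooses 0
  out0 <- optimizeExpressionPCs(e, gt, cfg, pcGrid = 0)
  expect_equal(out0$chosenK, 0)
  expect_error(optimizeExpressionPCs(e, gt, cfg, pcGrid = c(0, n + 1)),
               "below the sample count")
})
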