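mkModel <- function(variable = "v", weights = numeric(),
                    intercept = 0, r2 = 0.5) {
  new("SignatureModel", variable = variable, weights = weights,
      intercept = intercept, alpha = 0.1, lambda = 0.1, cvMse = 1,
      cvMseSd = 0.1, r2 = r2, nTrain = 50L, geneSubset = character())
}

test_that("a noise-free single-gene phenotype is recovered perfectly", {
  set.seed(41)
  r <- matrix(rnorm(50 * 100), 50, 100,
              dimnames = list(sprintf("g%03d", 1:50),
                              sprintf("s%03d", 1:100)))
  e <- withResid(r)
  y <- setNames(r["g010", ], colnames(r))
  fit <- fitSignature(y, e, minTrain = 20)
  expect_gte(cvR2(fit), 0.99)
  pred <- signatureValues(imputeSignatures(list(fit), e))[, 1]
  expect_gte(cor(pred, y), 0.999)
  expect_true("g010" %in% names(signatureWeights(fit)))
})

test_that("degenerate phenotypes are rejected", {
  r <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(sprintf("g%03d", 1:10),
                              sprintf("s%03d", 1:30)))
  e <- withResid(r)
  expect_error(fitSignature(setNames(rep(1, 30), colnames(r)), e),
               "constant")
  y <- setNames(rnorm(30), colnames(r))
  y[1:15] <- NA
  expect_error(fitSignature(y, e, minTrain = 20), "non-missing")
})

test_that("imputation applies the linear predictor to every sample", {
  r <- matrix(0, 2, 3, dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  r["gA", ] <- c(1, 0, 2)
  r["gB", ] <- c(3, 0, 1)
  e <- withResid(r)
  m <- mkModel(weights = c(gA = 2, gB = -1), intercept = 0.5)
  v <- signatureValues(imputeSignatures(list(v = m), e))
  ## 2*1 - 1*3 + 0.5 = -0.5 by hand
  expect_equal(unname(v[, 1]), c(-0.5, 0.5, 3.5))

  ## all-zero weights: intercept everywhere
  m0 <- mkModel(weights = numeric(), intercept = 0.7)
  v0 <- signatureValues(imputeSignatures(list(v = m0), e))
  expect_equal(unname(v0[, 1]), rep(0.7, 3))

  ## missing gene is a naming error
  mBad <- mkModel(weights = c(gMissing = 1))
  expect_error(imputeSignatures(list(v = mBad), e), "gMissing")
})

test_that("denoising replaces measured values with model predictions", {
  set.seed(42)
  r <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(sprintf("g%03d", 1:40),
                              sprintf("s%03d", 1:60)))
  e <- withResid(r)
  y <- setNames(r["g001", ] + rnorm(60, sd = 0.6), colnames(r))
  fit <- fitSignature(y, e, folds = 5, minTrain = 20)
  v <- signatureValues(imputeSignatures(list(fit), e))[, 1]
  ## the imputed value is the model prediction, not the observed y
  manual <- fit@intercept +
    as.numeric(crossprod(r[names(signatureWeights(fit)), , drop = FALSE],
                         signatureWeights(fit)))
  expect_equal(unname(v), manual)
  expect_gt(max(abs(v - y)), 0.01)
})

test_that("imputation is linear in the expression scale", {
  set.seed(43)
  r <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("g%03d", 1:10),
                              sprintf("s%03d", 1:20)))
  m <- mkModel(weights = c(g001 = 1.5, g007 = -2), intercept = 3)
  v1 <- signatureValues(imputeSignatures(list(v = m), withResid(r)))
  v3 <- signatureValues(imputeSignatures(list(v = m), withResid(3 * r)))
  expect_equal(v3 - 3, 3 * (v1 - 3), tolerance = 1e-12)
})

test_that("cross-validated r2 does not exceed the in-sample fit", {
  set.seed(44)
  r <- matrix(rnorm(60 * 80), 60, 80,
              dimnames = list(sprintf("g%03d", 1:60),
                              sprintf("s%03d", 1:80)))
  e <- withResid(r)
  y <- setNames(r["g005", ] + rnorm(80), colnames(r))
  fit <- fitSignature(y, e, folds = 10, minTrain = 20)
  pred <- signatureValues(imputeSignatures(list(fit), e))[, 1]
  r2In <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_lte(cvR2(fit), r2In + 1e-8)
})

test_that("adding pure-noise genes does not inflate the selected r2", {
  set.seed(45)
  n <- 120
  lat <- rnorm(n)
  r <- matrix(rnorm(40 * n), 40, n)
  r[1:10, ] <- r[1:10, ] + outer(rep(0.8, 10), lat)
  rownames(r) <- sprintf("g%03d", 1:40)
  colnames(r) <- sprintf("s%03d", 1:n)
  y <- setNames(lat + rnorm(n), colnames(r))
  fitSmall <- fitSignature(y, withResid(r), folds = 10, minTrain = 20)
  noise <- matrix(rnorm(500 * n), 500, n,
                  dimnames = list(sprintf("n%03d", 1:500), colnames(r)))
  fitBig <- fitSignature(y, withResid(rbind(r, noise)), folds = 10,
                         minTrain = 20)
  expect_lte(cvR2(fitBig), cvR2(fitSmall) + 0.02)
})

test_that("with alpha = 1 the causal gene dominates a noiseless fit", {
  set.seed(46)
  r <- matrix(rnorm(30 * 50), 30, 50,
              dimnames = list(sprintf("g%03d", 1:30),
                              sprintf("s%03d", 1:50)))
  y <- setNames(2 * r["g013", ], colnames(r))
  fit <- fitSignature(y, withResid(r), alpha = 1, folds = 10,
                      minTrain = 20)
  w <- signatureWeights(fit)
  expect_equal(names(which.max(abs(w))), "g013")
  expect_gt(abs(w["g013"]), 10 * max(abs(w[names(w) != "g013"]), 0.01))
})

test_that("restricted models report the subset intersection", {
  set.seed(47)
  r <- matrix(rnorm(80 * 90), 80, 90,
              dimnames = list(sprintf("g%03d", 1:80),
                              sprintf("s%03d", 1:90)))
  e <- withResid(r)
  y <- setNames(r["g002", ] + 0.1 * rnorm(90), colnames(r))
  ## a 53-name panel with only 48 present mirrors a published panel
  ## partially below detection
  panel <- c(sprintf("g%03d", 10:57), sprintf("absent%d", 1:5))
  cmp <- compareRestricted(y, e, panel, folds = 10, minTrain = 20)
  expect_equal(cmp$nSubsetFound, 48)
  ## causal gene g002 is outside the panel: restricted fit collapses
  expect_gte(cmp$r2Full, 0.9)
  expect_lte(cmp$r2Restricted, 0.05)

  ## subset = all genes reproduces the full fit
  cmpAll <- compareRestricted(y, e, rownames(r), folds = 10,
                              minTrain = 20)
  expect_equal(cmpAll$r2Restricted, cmpAll$r2Full, tolerance = 1e-12)

  expect_error(fitSignature(y, e, geneSubset = c("zz1", "zz2")),
               "none of the geneSubset")
})

test_that("signature correlations recover the generating block structure", {
  set.seed(48)
  n <- 250
  f <- rnorm(n)
  v1 <- sqrt(0.6) * f + sqrt(0.4) * rnorm(n)
  v2 <- sqrt(0.6) * f + sqrt(0.4) * rnorm(n)
  vals <- cbind(a = v1, b = v2, c = rnorm(n))
  rownames(vals) <- sprintf("s%03d", 1:n)
  sig <- new("SignatureMatrix", values = vals,
             selected = c(a = TRUE, b = TRUE, c = TRUE),
             models = list(mkModel("a"), mkModel("b"), mkModel("c")),
             r2Threshold = 0.01)
  ct <- correlateSignatures(sig)
  expect_equal(diag(ct$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(diag(ct$p), rep(0, 3), ignore_attr = TRUE)
  expect_true(ct$r["a", "b"] > 0.4 && ct$r["a", "b"] < 0.8)
  expect_false(ct$masked["a", "b"])
  expect_true(all(abs(ct$r - t(ct$r)) < 1e-12))

  ## a constant signature is masked with a warning
  vals2 <- cbind(vals, d = rep(1, n))
  sig2 <- new("SignatureMatrix", values = vals2,
              selected = setNames(rep(TRUE, 4), colnames(vals2)),
              models = c(sig@models, mkModel("d")), r2Threshold = 0.01)
  expect_warning(ct2 <- correlateSignatures(sig2), "constant")
  expect_true(all(ct2$masked["d", c("a", "b", "c")]))

  expect_error(correlateSignatures(
    new("SignatureMatrix", values = vals[, 1, drop = FALSE],
        selected = c(a = TRUE), models = list(mkModel("a")),
        r2Threshold = 0.01)), "two selected")
})

test_that("longitudinal validation handles exact and degenerate input", {
  s <- sprintf("s%02d", 1:20)
  obs1 <- setNames(rnorm(20), s)
  obs2 <- obs1 + setNames(rnorm(20), s)
  sig1 <- setNames(rnorm(20), s)
  sig2 <- sig1 + (obs2 - obs1) # signature deltas equal observed deltas
  out <- validateLongitudinal(obs1, obs2, sig1, sig2)
  expect_equal(out$rho, 1)
  expect_equal(out$n, 20)
  expect_error(validateLongitudinal(obs1[1:4], obs2[1:4], sig1[1:4],
                                    sig2[1:4]), "fewer than 5")
})

test_that("the CTRA panel ships with 53 genes", {
  genes <- ctraGenes()
  expect_length(genes, 53)
  expect_true(all(c("IL1B", "IFIT1", "IGLL1") %in% genes))
  expect_false(anyDuplicated(genes) > 0)
})
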