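## End-to-end driver: simulate -> preprocess -> signature -> eqtl ->
## gxe -> report, with every stage consuming the previous stage's
## plain-text artifacts, so any stage can be rerun in isolation.
## Outputs are deterministic functions of the configuration, making
## reruns byte-identical; each stage writes a JSON manifest recording
## the configuration hash, seeds and table sizes.

#' Assemble a pipeline configuration
#'
#' Bundles the synthetic-cohort configuration, the cis-scan
#' configuration and the signature/GxE settings with their standard
#' defaults (elastic-net alpha 0.1, 1 Mb cis window, MAF 0.1, 10\% FDR,
#' 1\%-variance signature selection).
#'
#' @param simConfig a \linkS4class{SimConfig}.
#' @param cisConfig a \linkS4class{CisScanConfig}.
#' @param alpha elastic-net mixing parameter.
#' @param folds cross-validation folds for signature fitting
#'   (\code{"loo"} or an integer).
#' @param r2Threshold signature selection threshold.
#' @param nNull pooled permutation null size per signature.
#' @param fdrLevel interaction FDR level.
#' @param marginalFdr FDR for marginal signature effects.
#' @param maxSignatures number of selected signatures carried into GxE
#'   mapping (ranked by cross-validated r2).
#' @param seed master seed.
#' @return a list with class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simConfig = sigQTL::simConfig(),
                           cisConfig = cisScanConfig(),
                           alpha = 0.1, folds = "loo",
                           r2Threshold = 0.01, nNull = 1e5,
                           fdrLevel = 0.10, marginalFdr = 0.10,
                           maxSignatures = 2, seed = 1) {
  structure(list(simConfig = simConfig, cisConfig = cisConfig,
                 alpha = alpha, folds = folds,
                 r2Threshold = r2Threshold, nNull = nNull,
                 fdrLevel = fdrLevel, marginalFdr = marginalFdr,
                 maxSignatures = maxSignatures, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.configHash <- function(config) {
  dump <- tempfile(fileext = ".json")
  on.exit(unlink(dump))
  desc <- list(
    sim = list(n = config$simConfig@nSamples,
               g = config$simConfig@nGenes,
               v = config$simConfig@nVariants,
               maf = config$simConfig@mafRange,
               blocks = as.list(config$simConfig@categoryBlocks),
               disp = config$simConfig@nbDispersion,
               lib = config$simConfig@libsizeRange,
               conf = config$simConfig@confounderCount,
               noise = config$simConfig@noiseSdPhenotype,
               miss = config$simConfig@missingFraction,
               rho = config$simConfig@blockCor,
               es = config$simConfig@effectSizes,
               seed = config$simConfig@seed),
    cis = list(win = config$cisConfig@windowBp,
               maf = config$cisConfig@mafMin,
               pmin = config$cisConfig@permMin,
               pmax = config$cisConfig@permMax,
               stop = config$cisConfig@adaptiveStopHits,
               fdr = config$cisConfig@fdrLevel,
               pcs = config$cisConfig@nExpressionPCs,
               seed = config$cisConfig@seed),
    rest = config[setdiff(names(config), c("simConfig", "cisConfig"))])
  jsonlite::write_json(desc, dump, digits = NA)
  unname(tools::md5sum(dump))
}

.writeManifest <- function(outdir, stage, config, info) {
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  hash <- .configHash(config)
  reproduced <- FALSE
  if (file.exists(path)) {
    prev <- jsonlite::read_json(path)
    reproduced <- identical(prev$config_hash[[1]], hash)
  }
  jsonlite::write_json(
    c(list(stage = stage, config_hash = hash, seed = config$seed,
           reproduced = reproduced), info),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.need <- function(outdir, files, stage) {
  missing <- files[!file.exists(file.path(outdir, files))]
  if (length(missing))
    stop("stage '", stage, "' requires artifact(s) from an earlier ",
         "stage: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

.loadPreprocessed <- function(outdir) {
  ann <- readAnnotation(file.path(outdir, "annotation.tsv"))
  expr <- readCounts(file.path(outdir, "counts.tsv"), ann)
  rs <- data.table::fread(file.path(outdir, "residual.tsv"),
                          sep = "\t", header = TRUE, data.table = FALSE)
  rm <- as.matrix(rs[, -1, drop = FALSE])
  rownames(rm) <- rs[[1]]
  expr <- expr[rownames(rm), ]
  lc <- data.table::fread(file.path(outdir, "logcpm.tsv"),
                          sep = "\t", header = TRUE, data.table = FALSE)
  lm_ <- as.matrix(lc[, -1, drop = FALSE])
  rownames(lm_) <- lc[[1]]
  assay(expr, "logcpm") <- lm_[rownames(rm), colnames(rm)]
  assay(expr, "resid") <- rm
  expr
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in their canonical order
#' (\code{simulate}, \code{preprocess}, \code{signature}, \code{eqtl},
#' \code{gxe}, \code{report}), reading earlier artifacts from
#' \code{outdir} and writing each stage's outputs and manifest there.
#' Rerunning with an unchanged configuration reproduces every artifact
#' byte for byte; the manifest then carries \code{reproduced = true}.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir output directory (created if needed).
#' @param stages subset of stages to run.
#' @return invisibly, the manifest paths written.
#' @export
runPipeline <- function(config, outdir,
                        stages = c("simulate", "preprocess", "signature",
                                   "eqtl", "gxe", "report")) {
  allStages <- c("simulate", "preprocess", "signature", "eqtl", "gxe",
                 "report")
  stages <- allStages[allStages %in% match.arg(stages, allStages,
                                               several.ok = TRUE)]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifests <- character()

  if ("simulate" %in% stages) {
    co <- simCohort(config$simConfig)
    writeCounts(co@expression, file.path(outdir, "counts.tsv"))
    writeDosages(co@genotypes, file.path(outdir, "dosages.tsv"))
    writeAnnotation(co@expression, file.path(outdir, "annotation.tsv"))
    writePhenotypes(co@phenotypes, file.path(outdir, "phenotypes.tsv"))
    writeTruth(co@truth, file.path(outdir, "truth.json"))
    cv <- co@covariates@raw
    .writeTsv(data.frame(sample_id = rownames(cv),
                         as.data.frame(lapply(cv, .fmtNum)),
                         check.names = FALSE),
              file.path(outdir, "covariates.tsv"))
    manifests <- c(manifests, .writeManifest(
      outdir, "simulate", config,
      list(n_samples = config$simConfig@nSamples,
           n_genes = config$simConfig@nGenes,
           n_variants = config$simConfig@nVariants)))
  }

  if ("preprocess" %in% stages) {
    .need(outdir, c("counts.tsv", "annotation.tsv", "covariates.tsv"),
          "preprocess")
    ann <- readAnnotation(file.path(outdir, "annotation.tsv"))
    expr <- readCounts(file.path(outdir, "counts.tsv"), ann)
    cov <- data.table::fread(file.path(outdir, "covariates.tsv"),
                             sep = "\t", header = TRUE,
                             data.table = FALSE)
    rownames(cov) <- cov$sample_id
    cov <- cov[, -1, drop = FALSE]
    expr <- normalizeLogCpm(filterGenes(expr))
    cs <- covariatePCs(cov, k = min(3, ncol(cov)))
    expr <- residualize(expr, cs)
    lc <- logCPM(expr)
    .writeTsv(data.frame(gene_id = rownames(lc),
                         as.data.frame(apply(lc, 2, .fmtNum,
                                             simplify = FALSE)),
                         check.names = FALSE),
              file.path(outdir, "logcpm.tsv"))
    rm <- residMatrix(expr)
    .writeTsv(data.frame(gene_id = rownames(rm),
                         as.data.frame(apply(rm, 2, .fmtNum,
                                             simplify = FALSE)),
                         check.names = FALSE),
              file.path(outdir, "residual.tsv"))
    manifests <- c(manifests, .writeManifest(
      outdir, "preprocess", config,
      list(n_genes_kept = nrow(rm),
           pc_variance = sum(varianceExplained(cs)))))
  }

  if ("signature" %in% stages) {
    .need(outdir, c("residual.tsv", "phenotypes.tsv"), "signature")
    expr <- .loadPreprocessed(outdir)
    pheno <- readPhenotypes(file.path(outdir, "phenotypes.tsv"))
    models <- fitAllSignatures(pheno, expr, alpha = config$alpha,
                               folds = config$folds)
    sig <- imputeSignatures(models, expr,
                            r2Threshold = config$r2Threshold)
    writeSignatureWeights(models,
                          file.path(outdir, "signature_weights.tsv"))
    writeSignatureMatrix(sig, file.path(outdir, "signature_matrix.tsv"))
    stats <- data.frame(
      variable = names(models),
      r2 = .fmtNum(vapply(models, cvR2, numeric(1))),
      cv_mse = .fmtNum(vapply(models, function(m) m@cvMse, numeric(1))),
      cv_mse_sd = .fmtNum(vapply(models, function(m) m@cvMseSd,
                                 numeric(1))),
      n_train = vapply(models, function(m) m@nTrain, integer(1)),
      selected = selectedSignatures(sig)[names(models)])
    .writeTsv(stats, file.path(outdir, "signature_stats.tsv"))
    manifests <- c(manifests, .writeManifest(
      outdir, "signature", config,
      list(n_models = length(models),
           n_selected = sum(selectedSignatures(sig)))))
  }

  if ("eqtl" %in% stages) {
    .need(outdir, c("residual.tsv", "dosages.tsv"), "eqtl")
    expr <- .loadPreprocessed(outdir)
    gt <- readDosages(file.path(outdir, "dosages.tsv"))
    rec <- mapCisEqtl(expr, gt, config$cisConfig)
    writeEqtlResults(rec, file.path(outdir, "eqtl_results.txt"))
    manifests <- c(manifests, .writeManifest(
      outdir, "eqtl", config,
      list(n_genes_tested = nrow(rec), n_egenes = sum(rec$eGene))))
  }

  if ("gxe" %in% stages) {
    .need(outdir, c("residual.tsv", "dosages.tsv", "eqtl_results.txt",
                    "signature_matrix.tsv", "signature_stats.tsv"),
          "gxe")
    expr <- .loadPreprocessed(outdir)
    gt <- readDosages(file.path(outdir, "dosages.tsv"))
    eq <- readEqtlResults(file.path(outdir, "eqtl_results.txt"))
    eq$qvalue <- storeyQvalue(eq$permPBeta)
    leads <- eq[eq$qvalue <= config$cisConfig@fdrLevel, , drop = FALSE]
    if (!nrow(leads)) leads <- eq[order(eq$permPBeta), ][1, , drop = FALSE]
    stats <- data.table::fread(file.path(outdir, "signature_stats.tsv"),
                               sep = "\t", header = TRUE,
                               data.table = FALSE)
    sm <- data.table::fread(file.path(outdir, "signature_matrix.tsv"),
                            sep = "\t", header = TRUE,
                            data.table = FALSE)
    vals <- as.matrix(sm[, -1, drop = FALSE])
    rownames(vals) <- sm[[1]]
    picked <- stats$variable[stats$selected]
    picked <- picked[order(-as.numeric(stats$r2[stats$selected]))]
    picked <- head(picked, config$maxSignatures)
    if (!length(picked)) picked <- stats$variable[which.max(stats$r2)]
    recs <- list()
    for (s in picked) {
      e <- inverseNormalTransform(vals[, s])
      tab <- mapInteractions(expr, gt, leads,
                             setNames(e, rownames(vals)),
                             intApplied = TRUE)
      tab$signature <- s
      ns <- buildPermutationNull(expr, gt, leads, e,
                                 nNull = config$nNull,
                                 seed = config$seed + match(s, picked),
                                 signatureName = s, intApplied = TRUE)
      writeNullStore(ns, file.path(outdir,
                                   paste0("null_", s, ".txt.gz")))
      recs[[s]] <- correctAndQvalue(tab, ns,
                                    fdrLevel = config$fdrLevel)
    }
    gxe <- do.call(rbind, recs)
    rownames(gxe) <- NULL
    writeGxeResults(gxe, file.path(outdir, "gxe_results.tsv"))
    manifests <- c(manifests, .writeManifest(
      outdir, "gxe", config,
      list(n_tests = nrow(gxe),
           n_significant = sum(gxe$significant))))
  }

  if ("report" %in% stages) {
    .need(outdir, c("eqtl_results.txt", "gxe_results.tsv"), "report")
    eq <- readEqtlResults(file.path(outdir, "eqtl_results.txt"))
    eq$qvalue <- storeyQvalue(eq$permPBeta)
    gx <- readGxeResults(file.path(outdir, "gxe_results.tsv"))
    rep_ <- list(
      n_genes_tested = nrow(eq),
      n_egenes = sum(eq$qvalue <= config$cisConfig@fdrLevel),
      n_gxe_tests = nrow(gx),
      n_gxe_significant = sum(
        gx$q_interaction_permcorrected <= config$fdrLevel),
      n_gxe_genes = length(unique(gx$gene[
        gx$q_interaction_permcorrected <= config$fdrLevel])))
    jsonlite::write_json(rep_, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifests <- c(manifests, .writeManifest(outdir, "report", config,
                                             rep_))
  }
  invisible(manifests)
}
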