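## Readers and writers for the pipeline's plain-text interchange
## formats. Floating-point output uses 6 significant digits; integers
## are written unformatted. Chromosome names are normalized internally
## by stripping any "chr" prefix.

.fmtNum <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

.writeTsv <- function(df, path, colNames = TRUE, sep = "\t") {
  data.table::fwrite(df, path, sep = sep, col.names = colNames,
                     quote = FALSE, na = "NA")
}

#' Read a genotype dosage matrix
#'
#' Accepts either the package's TSV dialect (columns \code{id},
#' \code{chrom}, \code{pos}, then one column per sample) or a VCF whose
#' FORMAT carries a \code{DS} dosage field (parsed with the vcfR
#' package). Dosages must lie in [0, 2].
#'
#' @param path TSV or VCF file.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readDosages <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF"))
    return(.readDosagesVcf(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(dt)))
    stop("dosage TSV must start with columns id, chrom, pos")
  d <- as.matrix(dt[, setdiff(names(dt), need), drop = FALSE])
  bad <- which(rowSums(d < 0 | d > 2, na.rm = TRUE) > 0)
  if (length(bad))
    stop(sprintf("dosage outside [0, 2] at line %d of %s",
                 bad[1] + 1L, path))
  if (anyDuplicated(dt$id))
    stop("duplicated variant id(s): ",
         paste(head(unique(dt$id[duplicated(dt$id)]), 5), collapse = ", "))
  rownames(d) <- dt$id
  new("GenotypeMatrix", SummarizedExperiment(
    assays = list(dosage = d),
    rowData = DataFrame(chrom = .normChrom(dt$chrom), pos = dt$pos,
                        row.names = dt$id)))
}

.readDosagesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF dosages requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(ds) <- ids
  if (any(ds < 0 | ds > 2, na.rm = TRUE))
    stop("VCF DS dosage outside [0, 2]")
  new("GenotypeMatrix", SummarizedExperiment(
    assays = list(dosage = ds),
    rowData = DataFrame(chrom = .normChrom(fix[, "CHROM"]),
                        pos = as.numeric(fix[, "POS"]),
                        row.names = ids)))
}

#' @rdname readDosages
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @export
writeDosages <- function(genotypes, path) {
  vi <- variantInfo(genotypes)
  d <- dosages(genotypes)
  df <- data.frame(id = vi$id, chrom = vi$chrom, pos = vi$pos,
                   stringsAsFactors = FALSE)
  ## preserve integer hard calls; format fractional dosages compactly
  ddf <- as.data.frame(d)
  ## 7 significant digits so dosages in [0, 2] round-trip within 1e-6
  if (any(d != round(d), na.rm = TRUE))
    ddf[] <- lapply(ddf, function(x) sprintf("%.7g", x))
  .writeTsv(cbind(df, ddf), path)
  invisible(path)
}

#' Write dosages as a minimal VCF with a DS FORMAT field
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @export
writeVcfDosages <- function(genotypes, path) {
  vi <- variantInfo(genotypes)
  d <- dosages(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(d)),
                     collapse = "\t")), con)
  body <- cbind(vi$chrom, vi$pos, vi$id, "A", "G", ".", ".", ".", "DS",
                matrix(sprintf("%.7g", d), nrow = nrow(d)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read/write an expression count matrix
#'
#' TSV with a \code{gene_id} column followed by one column per sample.
#' An annotation (from \code{\link{readAnnotation}}) supplies the gene
#' coordinates required by an \linkS4class{ExpressionMatrix}.
#'
#' @param path counts TSV.
#' @param annotation data.frame with \code{gene_id}, \code{chrom},
#'   \code{tss}, \code{strand}.
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
readCounts <- function(path, annotation) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (names(dt)[1] != "gene_id")
    stop("counts TSV must have a leading gene_id column")
  if (anyDuplicated(dt$gene_id))
    stop("duplicated gene id(s): ",
         paste(head(unique(dt$gene_id[duplicated(dt$gene_id)]), 5),
               collapse = ", "))
  if (anyDuplicated(names(dt)[-1]))
    stop("duplicated sample id(s): ",
         paste(head(unique(names(dt)[-1][duplicated(names(dt)[-1])]), 5),
               collapse = ", "))
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt$gene_id
  ann <- annotation[match(rownames(m), annotation$gene_id), ]
  if (anyNA(ann$gene_id))
    stop("annotation is missing gene(s): ",
         paste(head(rownames(m)[is.na(ann$gene_id)], 5), collapse = ", "))
  new("ExpressionMatrix", SummarizedExperiment(
    assays = list(counts = m),
    rowData = DataFrame(chrom = ann$chrom, tss = ann$tss,
                        strand = ann$strand, row.names = rownames(m))))
}

#' @rdname readCounts
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @export
writeCounts <- function(expr, path) {
  m <- counts(expr)
  .writeTsv(data.frame(gene_id = rownames(m), as.data.frame(m),
                       check.names = FALSE), path)
  invisible(path)
}

#' Read/write the BED-like gene annotation
#'
#' Columns \code{gene_id}, \code{chrom}, \code{start} (0-based, as in
#' BED), \code{end} (1-based inclusive), \code{strand}. On reading, the
#' strand-aware TSS is derived: \code{start + 1} for plus-strand genes
#' and \code{end} for minus-strand genes.
#'
#' @param path annotation TSV.
#' @return data.frame with \code{gene_id}, \code{chrom}, \code{tss},
#'   \code{strand} (plus the raw interval).
#' @export
readAnnotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(dt)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  dt$tss <- ifelse(dt$strand == "-", dt$end, dt$start + 1)
  dt$chrom <- .normChrom(dt$chrom)
  dt
}

#' @rdname readAnnotation
#' @param annotation data.frame with \code{gene_id}, \code{chrom},
#'   \code{tss}, \code{strand} (e.g. \code{geneInfo()}), or an
#'   \linkS4class{ExpressionMatrix}.
#' @param geneLength interval length written for each gene.
#' @export
writeAnnotation <- function(annotation, path, geneLength = 10000) {
  ann <- if (is(annotation, "ExpressionMatrix")) geneInfo(annotation)
         else annotation
  minus <- ann$strand == "-"
  start1 <- ifelse(minus, pmax(1, ann$tss - geneLength + 1), ann$tss)
  end1 <- ifelse(minus, ann$tss, ann$tss + geneLength - 1)
  .writeTsv(data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                       start = start1 - 1L, end = end1,
                       strand = ann$strand), path)
  invisible(path)
}

#' Read/write the phenotype table
#'
#' Sample rows; the first header row names the variables, the second
#' header row carries their category labels.
#'
#' @param path phenotype TSV.
#' @return a \linkS4class{PhenotypeTable}.
#' @export
readPhenotypes <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cats <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  dt <- data.table::fread(text = lines[-2], sep = "\t", header = TRUE,
                          data.table = FALSE)
  vars <- hdr[-1]
  df <- dt[, vars, drop = FALSE]
  rownames(df) <- dt[[1]]
  new("PhenotypeTable", data = df,
      categories = setNames(cats[-1], vars))
}

#' @rdname readPhenotypes
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @export
writePhenotypes <- function(pheno, path) {
  df <- phenoValues(pheno)
  cats <- phenoCategories(pheno)
  con <- file(path, "w")
  writeLines(c(paste(c("sample_id", colnames(df)), collapse = "\t"),
               paste(c("category", unname(cats[colnames(df)])),
                     collapse = "\t")), con)
  close(con)
  body <- data.frame(sample_id = rownames(df),
                     lapply(df, .fmtNum), check.names = FALSE)
  data.table::fwrite(body, path, sep = "\t", col.names = FALSE,
                     append = TRUE, quote = FALSE)
  invisible(path)
}

#' Read an external TWAS summary table
#'
#' Expects columns \code{gene}, \code{trait}, \code{p} and a logical
#' or 0/1 \code{significant} flag.
#'
#' @param path TWAS TSV.
#' @return data.frame.
#' @export
readTwas <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("gene", "trait", "significant")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("TWAS table is missing column(s): ",
         paste(miss, collapse = ", "))
  dt$significant <- as.logical(dt$significant)
  dt
}

.EQTL_COLS <- c("gene", "nVariants", "betaShape1", "betaShape2", "dummy",
                "bestVariant", "tssDistance", "nominalP", "slope",
                "permPDirect", "permPBeta")

#' Read/write cis-eQTL results (11-column space-delimited)
#'
#' The on-disk layout is the classic space-delimited permutation-pass
#' format: gene id, number of variants tested, the two MLE shape
#' parameters of the beta approximation, a constant dummy column, the
#' lead variant and its TSS distance, the nominal p-value and slope,
#' and the direct and beta-approximated permutation p-values. No
#' header.
#'
#' @param records data.frame from \code{\link{mapCisEqtl}}.
#' @param path output file.
#' @export
writeEqtlResults <- function(records, path) {
  df <- records[, .EQTL_COLS]
  for (col in c("betaShape1", "betaShape2", "nominalP", "slope",
                "permPDirect", "permPBeta"))
    df[[col]] <- .fmtNum(df[[col]])
  .writeTsv(df, path, colNames = FALSE, sep = " ")
  invisible(path)
}

#' @rdname writeEqtlResults
#' @export
readEqtlResults <- function(path) {
  dt <- data.table::fread(path, sep = " ", header = FALSE,
                          data.table = FALSE)
  if (ncol(dt) != length(.EQTL_COLS))
    stop("expected ", length(.EQTL_COLS), " space-delimited columns")
  names(dt) <- .EQTL_COLS
  dt
}

.GXE_COLS <- c("gene", "variant",
               paste0("p_", .GXE_TERMS), paste0("b_", .GXE_TERMS),
               paste0("se_", .GXE_TERMS), paste0("q_", .GXE_TERMS),
               "signature", "p_interaction_permcorrected",
               "q_interaction_permcorrected")

#' Read/write GxE results (21-column tab-delimited)
#'
#' Column order: gene and variant ids; p-values, estimates, standard
#' errors and q-values of the intercept, dosage, signature and
#' interaction terms; the signature name; and the
#' permutation-corrected interaction p-value with its q-value.
#'
#' @param records data.frame from \code{\link{mapInteractions}} after
#'   \code{\link{correctAndQvalue}}.
#' @param path output file.
#' @export
writeGxeResults <- function(records, path) {
  df <- records[, .GXE_COLS]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmtNum)
  .writeTsv(df, path)
  invisible(path)
}

#' @rdname writeGxeResults
#' @export
readGxeResults <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (!identical(names(dt), .GXE_COLS))
    stop("unexpected GxE result columns")
  dt
}

#' Read/write a permutation null store
#'
#' Gzipped text: a header line carrying the signature name, seed and
#' count, then one null p-value per line.
#'
#' @param nullStore a \linkS4class{NullStore}.
#' @param path output file (".gz" recommended).
#' @export
writeNullStore <- function(nullStore, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#signature=%s;seed=%d;nNull=%d",
                     nullStore@signature, nullStore@seed,
                     nullStore@nNull), con)
  writeLines(format(nullValues(nullStore), digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname writeNullStore
#' @export
readNullStore <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^#", "", lines[1])
  kv <- strsplit(strsplit(hdr, ";")[[1]], "=")
  vals <- setNames(vapply(kv, `[`, character(1), 2),
                   vapply(kv, `[`, character(1), 1))
  new("NullStore", signature = vals[["signature"]],
      nullP = as.numeric(lines[-1]),
      nNull = as.integer(vals[["nNull"]]),
      seed = as.integer(vals[["seed"]]))
}

#' Write signature model weights as a gene x variable table
#'
#' Genes in rows, signatures in columns; zeros for genes a model does
#' not use.
#'
#' @param models named list of \linkS4class{SignatureModel}.
#' @param path output TSV.
#' @param omitZeroRows drop genes with no nonzero weight anywhere.
#' @export
writeSignatureWeights <- function(models, path, omitZeroRows = TRUE) {
  genes <- sort(unique(unlist(lapply(models, function(m)
    names(signatureWeights(m))))))
  if (!length(genes)) genes <- character()
  m <- matrix(0, length(genes), length(models),
              dimnames = list(genes, names(models)))
  for (v in names(models)) {
    w <- signatureWeights(models[[v]])
    m[names(w), v] <- w
  }
  if (!omitZeroRows && length(genes) == 0) m <- m
  df <- data.frame(gene_id = rownames(m),
                   as.data.frame(apply(m, 2, .fmtNum, simplify = FALSE)),
                   check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' Write imputed signature values (samples x variables)
#'
#' @param sig a \linkS4class{SignatureMatrix}.
#' @param path output TSV.
#' @export
writeSignatureMatrix <- function(sig, path) {
  v <- signatureValues(sig)
  df <- data.frame(sample_id = rownames(v),
                   as.data.frame(apply(v, 2, .fmtNum,
                                       simplify = FALSE)),
                   check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' Serialize/restore a TruthSet as JSON
#'
#' Full-precision JSON so the ground truth round-trips losslessly.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param path output JSON file.
#' @export
writeTruth <- function(truth, path) {
  obj <- list(
    latentTraits = truth@latentTraits, betaG = truth@betaG,
    betaE = truth@betaE, betaGxe = truth@betaGxe,
    assignedVariant = truth@assignedVariant,
    assignedVariable = truth@assignedVariable,
    confounderLoadings = truth@confounderLoadings,
    confounders = truth@confounders,
    cellLoadings = truth@cellLoadings, cellProps = truth@cellProps,
    baseLogMean = truth@baseLogMean,
    geneIds = names(truth@betaG),
    dimnames = list(latent = dimnames(truth@latentTraits),
                    conf = dimnames(truth@confounders),
                    confLoad = dimnames(truth@confounderLoadings),
                    cellLoad = dimnames(truth@cellLoadings),
                    cellProps = dimnames(truth@cellProps)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       na = "string")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixNA <- function(x) {
    x[x == "NA"] <- NA
    x
  }
  setDim <- function(m, dn) {
    m <- as.matrix(m)
    dimnames(m) <- dn
    m
  }
  g <- unlist(o$geneIds)
  nm <- function(x) setNames(unlist(x), g)
  new("TruthSet",
      latentTraits = setDim(o$latentTraits, o$dimnames$latent),
      betaG = nm(o$betaG), betaE = nm(o$betaE),
      betaGxe = nm(o$betaGxe),
      assignedVariant = unname(fixNA(unlist(o$assignedVariant))),
      assignedVariable = unname(fixNA(unlist(o$assignedVariable))),
      confounderLoadings = setDim(o$confounderLoadings,
                                  o$dimnames$confLoad),
      confounders = setDim(o$confounders, o$dimnames$conf),
      cellLoadings = setDim(o$cellLoadings, o$dimnames$cellLoad),
      cellProps = setDim(o$cellProps, o$dimnames$cellProps),
      baseLogMean = nm(o$baseLogMean))
}
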