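#' Write / read a feature-by-sample matrix as TSV
#'
#' Features as rows, samples as columns, header row, `NA` for missing.
#'
#' @param x numeric matrix.
#' @param file path.
#' @return `writeMatrixTsv` returns the path invisibly; `readMatrixTsv`
#'   the matrix.
#' @export
writeMatrixTsv <- function(x, file) {
  df <- data.frame(feature = rownames(x), x, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(file) {
  df <- read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> confounder regression -> attenuation (potentials, mixture
#' classification, complex enrichment) -> CNV and mRNA association screens
#' (intersection, colocalization deduplication, control status) -> phospho
#' screen -> tissue-panel validation -> eQTL GWAS-tagging stratification,
#' writing stage TSV outputs and a JSON manifest with parameters, seed and
#' file checksums. Reruns with the same config are bit-identical.
#'
#' @param outDir output directory (created if needed).
#' @param seed master RNG seed, recorded in the manifest.
#' @param simulation list of [simulationConfig()] arguments.
#' @param fdrThreshold FDR cutoff for the screens (strict `<`).
#' @param minPairs minimum complete pairs for attenuation correlations.
#' @param stages character vector of stages to run, in dependency order.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
runPipeline <- function(outDir, seed = 1L,
                        simulation = list(),
                        fdrThreshold = 0.05, minPairs = 20L,
                        stages = c("simulate", "attenuation",
                                   "associations", "phospho", "tissues",
                                   "eqtl")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(); out <- list()
  emit <- function(x, name) {
    f <- file.path(outDir, name)
    if (is.matrix(x)) writeMatrixTsv(x, f)
    else write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  stopifnot("simulate" %in% stages)
  simCfg <- do.call(simulationConfig, c(simulation, list(seed = seed)))
  sim <- simulateCohort(simCfg)
  cohort <- sim$cohort; truth <- sim$truth
  out$truth <- truth
  emit(cnvMatrix(cohort), "cnv.tsv")
  emit(mrnaMatrix(cohort), "mrna.tsv")
  emit(proteinMatrix(cohort), "protein.tsv")
  if (nrow(phosphoMatrix(cohort))) emit(phosphoMatrix(cohort), "phospho.tsv")
  emit(cbind(sample = rownames(sampleCovariates(cohort)),
             sampleCovariates(cohort)), "covariates.tsv")
  emit(trueEdges(truth), "truth_edges.tsv")

  ## confounder regression feeds every downstream stage
  resid <- omicsCohort(
    cnv = cnvMatrix(cohort),
    mrna = regressConfounders(mrnaMatrix(cohort), sampleCovariates(cohort)),
    protein = regressConfounders(proteinMatrix(cohort),
                                 sampleCovariates(cohort)),
    phospho = phosphoMatrix(cohort), phosphoMap = phosphoMap(cohort),
    covariates = sampleCovariates(cohort))
  out$cohort <- resid

  if ("attenuation" %in% stages) {
    att <- computeAttenuation(resid, minPairs = minPairs)
    cls <- classifyAttenuation(setNames(att$potential, att$gene),
                               seed = seed)
    att$class <- as.character(cls$classes[att$gene])
    out$attenuation <- att
    out$classification <- cls
    emit(att, "attenuation.tsv")
    enr <- enrichComplexes(att$gene[att$class != "non_attenuated"],
                           complexSets(truth), att$gene)
    out$enrichment <- enr
    emit(enr, "complex_enrichment.tsv")
  }

  if ("associations" %in% stages) {
    pairs <- interactionPairs(truth, seed = seed)
    out$pairs <- pairs
    cnvRes <- screenPairs(resid, pairs, variant = "cnv")
    mrnaRes <- screenPairs(resid, pairs, variant = "mrna")
    sig <- intersectVariants(cnvRes, mrnaRes, threshold = fdrThreshold)
    final <- deduplicateColocalized(sig, geneMap(truth), cnvMatrix(cohort))
    out$cnvScreen <- cnvRes; out$mrnaScreen <- mrnaRes
    out$significant <- sig; out$final <- final
    emit(cnvRes, "screen_cnv.tsv"); emit(mrnaRes, "screen_mrna.tsv")
    emit(final, "associations_final.tsv")
    if (nrow(final)) {
      cs <- classifyControlStatus(final)
      out$controlStatus <- cs
      emit(cs, "control_status.tsv")
    }
  }

  if ("phospho" %in% stages && nrow(phosphoMatrix(cohort))) {
    ph <- screenPhospho(resid, out$pairs, proteinPairs = out$final,
                        threshold = fdrThreshold)
    out$phospho <- ph
    emit(ph$results, "screen_phospho.tsv")
    emit(ph$final, "phospho_final.tsv")
  }

  if ("tissues" %in% stages && !is.null(out$significant)) {
    panel <- simulateTissuePanel(truth, seed = seed)
    cls <- ifelse(paste(out$pairs$x, out$pairs$y) %in%
                    paste(out$final$x, out$final$y)[out$final$fdr < 0.01],
                  "highsig",
                  ifelse(paste(out$pairs$x, out$pairs$y) %in%
                           paste(out$final$x, out$final$y), "sig", "nonsig"))
    tp <- data.frame(x = out$pairs$x, y = out$pairs$y, class = cls,
                     stringsAsFactors = FALSE)
    out$tissue <- stratifiedPairCorrelations(
      structure(list(mrna = panel$mrna, protein = panel$protein,
                     tissues = colnames(panel$mrna)), class = "TissuePanel"),
      tp)
    emit(out$tissue$correlations, "tissue_correlations.tsv")
  }

  if ("eqtl" %in% stages && !is.null(out$classification)) {
    tabs <- simulateEqtlTables(truth, seed = seed)
    surv <- filterTissueConsistency(tabs$eqtl)
    blocks <- buildBlocks(surv, tabs$ld)
    tagged <- tagBlocks(blocks, tabs$ld, tabs$gwas)
    classes <- setNames(as.character(out$classification$classes),
                        names(out$classification$classes))
    out$eqtl <- taggingFractionByClass(tagged, classes,
                                       attenuation = out$attenuation)
    emit(out$eqtl, "eqtl_fractions.tsv")
  }

  manifest <- list(
    seed = seed, stages = stages, fdrThreshold = fdrThreshold,
    minPairs = minPairs,
    simulation = simulation,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

#' Summarize a pipeline run directory
#'
#' Reads the stage TSV outputs of [runPipeline()] and prints and returns
#' summary counts: attenuation classes, association counts by screen,
#' control status, tissue strata sizes and eQTL tagging fractions.
#'
#' @param runDir output directory of a completed [runPipeline()] run.
#' @return Invisibly, a list of summary tables (also written to
#'   `summary.json` in the run directory).
#' @export
reportRun <- function(runDir) {
  if (!file.exists(file.path(runDir, "manifest.json")))
    stop("no manifest.json in ", runDir, "; incomplete run")
  smry <- list()
  rd <- function(name) {
    f <- file.path(runDir, name)
    if (file.exists(f)) read.delim(f, stringsAsFactors = FALSE) else NULL
  }
  att <- rd("attenuation.tsv")
  if (!is.null(att)) {
    smry$attenuationClasses <- as.list(table(att$class))
    cat("Attenuation classes:\n"); print(table(att$class))
  }
  for (nm in c(cnv = "screen_cnv.tsv", mrna = "screen_mrna.tsv",
               final = "associations_final.tsv",
               phospho = "phospho_final.tsv")) {
    x <- rd(nm)
    if (!is.null(x))
      smry$associationCounts[[sub("\\.tsv$", "", nm)]] <-
        if ("fdr" %in% names(x)) sum(x$fdr < 0.05) else nrow(x)
  }
  cs <- rd("control_status.tsv")
  if (!is.null(cs)) {
    smry$controlStatus <- as.list(table(cs$status))
    cat("Control status:\n"); print(table(cs$status))
  }
  tc <- rd("tissue_correlations.tsv")
  if (!is.null(tc)) smry$tissueStrata <- as.list(table(tc$class))
  eq <- rd("eqtl_fractions.tsv")
  if (!is.null(eq)) smry$eqtlFractions <- eq
  jsonlite::write_json(smry, file.path(runDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(smry)
}
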