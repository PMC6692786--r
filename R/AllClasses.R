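#' @import methods
#' @importFrom stats rnorm runif rbinom cor sd median quantile pchisq phyper
#'   p.adjust wilcox.test lm model.matrix complete.cases setNames rpois
#'   ks.test pnorm na.omit aggregate
#' @importFrom utils head read.delim write.table
NULL

GISTIC_LEVELS <- -2:2

#' Simulation configuration for synthetic multi-omics cohorts
#'
#' Holds every generative parameter of [simulateCohort()]. Defaults encode
#' the cohort conditions the analysis is benchmarked under: 368 samples,
#' 2,000 genes, 42% of genes attenuated (one quarter of those highly
#' attenuated, buffering strength 0.8; the rest lowly attenuated, 0.4),
#' GISTIC copy-number levels -2..2 drawn per colocalization block, and
#' additive covariate effects on the log scale.
#'
#' @slot nSamples,nGenes,nComplexes,nChromosomes integer scalars.
#' @slot complexSizeRange integer vector (min, max) of complex sizes.
#' @slot fracAttenuated proportion of genes buffered at the protein level.
#' @slot fracHighAttenuated proportion of attenuated genes in the high class.
#' @slot bufferingHigh,bufferingLow buffering strength b in `[0, 1]` per class
#'   (1 = protein fully tracks the controlling subunit, 0 = tracks own mRNA).
#' @slot cnvLevelProbs probability vector over GISTIC levels -2..2.
#' @slot mrnaDosageSlope slope of mRNA on CNV.
#' @slot noiseSdMrna,noiseSdProtein,noiseSdPhospho residual s.d. per layer.
#' @slot covariateEffectSds named s.d. of per-gene covariate effects
#'   (cancer_type, batch, technology, age, gender).
#' @slot colocalizationBlockSize genes per chromosomal block sharing one CNV
#'   profile.
#' @slot fracColocalized fraction of true edges whose controller gets a
#'   colocalized passenger gene in the candidate pair list.
#' @slot fracPhosphoRegulatory fraction of true edges modulated by a
#'   regulatory phosphosite on the controller.
#' @slot phosphoBeta effect size of a regulatory phosphosite.
#' @slot missingRateProtein,missingRatePhospho MCAR missingness rates.
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   cohorts.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nSamples = "integer", nGenes = "integer", nComplexes = "integer",
  complexSizeRange = "integer", fracAttenuated = "numeric",
  fracHighAttenuated = "numeric", bufferingHigh = "numeric",
  bufferingLow = "numeric", cnvLevelProbs = "numeric",
  mrnaDosageSlope = "numeric", noiseSdMrna = "numeric",
  noiseSdProtein = "numeric", noiseSdPhospho = "numeric",
  covariateEffectSds = "numeric", nChromosomes = "integer",
  colocalizationBlockSize = "integer", fracColocalized = "numeric",
  fracPhosphoRegulatory = "numeric", phosphoBeta = "numeric",
  missingRateProtein = "numeric", missingRatePhospho = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  prop <- c(fracAttenuated = object@fracAttenuated,
            fracHighAttenuated = object@fracHighAttenuated,
            bufferingHigh = object@bufferingHigh,
            bufferingLow = object@bufferingLow,
            fracColocalized = object@fracColocalized,
            fracPhosphoRegulatory = object@fracPhosphoRegulatory,
            missingRateProtein = object@missingRateProtein,
            missingRatePhospho = object@missingRatePhospho)
  bad <- names(prop)[is.na(prop) | prop < 0 | prop > 1]
  if (length(bad))
    msg <- c(msg, paste0("proportions outside [0, 1]: ",
                         paste(bad, collapse = ", ")))
  if (length(object@cnvLevelProbs) != 5L || any(object@cnvLevelProbs < 0) ||
      abs(sum(object@cnvLevelProbs) - 1) > 1e-8)
    msg <- c(msg, "cnvLevelProbs must be 5 nonnegative values summing to 1")
  if (length(object@complexSizeRange) != 2L ||
      object@complexSizeRange[1] > object@complexSizeRange[2] ||
      object@complexSizeRange[1] < 2L)
    msg <- c(msg, "complexSizeRange must be (min, max) with 2 <= min <= max")
  if (any(c(object@noiseSdMrna, object@noiseSdProtein,
            object@noiseSdPhospho) < 0))
    msg <- c(msg, "noise standard deviations must be nonnegative")
  if (any(c(object@nSamples, object@nGenes, object@nComplexes,
            object@nChromosomes, object@colocalizationBlockSize) < 1L))
    msg <- c(msg, "counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nSamples,nGenes,nComplexes,nChromosomes cohort dimensions.
#' @param complexSizeRange (min, max) protein-complex sizes.
#' @param fracAttenuated fraction of genes with protein-level buffering.
#' @param fracHighAttenuated fraction of attenuated genes in the high class.
#' @param bufferingHigh,bufferingLow per-class buffering strength in `[0, 1]`.
#' @param cnvLevelProbs probabilities of GISTIC levels -2, -1, 0, 1, 2.
#' @param mrnaDosageSlope slope of mRNA on CNV dosage.
#' @param noiseSdMrna,noiseSdProtein,noiseSdPhospho residual s.d. per layer.
#' @param covariateEffectSds named numeric s.d. of per-gene covariate effects.
#' @param colocalizationBlockSize adjacent genes sharing one CNV profile.
#' @param fracColocalized fraction of edges given a colocalized passenger.
#' @param fracPhosphoRegulatory fraction of edges with a regulatory
#'   phosphosite on the controller.
#' @param phosphoBeta regulatory phosphosite effect size.
#' @param missingRateProtein,missingRatePhospho MCAR missingness rates.
#' @param seed integer RNG seed.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nSamples = 60, nGenes = 200, nComplexes = 20)
#' @export
simulationConfig <- function(nSamples = 368, nGenes = 2000, nComplexes = 180,
                             complexSizeRange = c(3, 10),
                             fracAttenuated = 0.42, fracHighAttenuated = 0.25,
                             bufferingHigh = 0.8, bufferingLow = 0.4,
                             cnvLevelProbs = c(0.05, 0.25, 0.40, 0.25, 0.05),
                             mrnaDosageSlope = 1,
                             noiseSdMrna = 0.5, noiseSdProtein = 0.5,
                             noiseSdPhospho = 0.3,
                             covariateEffectSds = c(cancer_type = 0.3,
                                                    batch = 0.2,
                                                    technology = 0.2,
                                                    age = 0.1, gender = 0.1),
                             nChromosomes = 22,
                             colocalizationBlockSize = 3,
                             fracColocalized = 0.1,
                             fracPhosphoRegulatory = 0.2, phosphoBeta = 0.4,
                             missingRateProtein = 0.15,
                             missingRatePhospho = 0.3, seed = 1L) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
      nComplexes = as.integer(nComplexes),
      complexSizeRange = as.integer(complexSizeRange),
      fracAttenuated = fracAttenuated,
      fracHighAttenuated = fracHighAttenuated,
      bufferingHigh = bufferingHigh, bufferingLow = bufferingLow,
      cnvLevelProbs = cnvLevelProbs, mrnaDosageSlope = mrnaDosageSlope,
      noiseSdMrna = noiseSdMrna, noiseSdProtein = noiseSdProtein,
      noiseSdPhospho = noiseSdPhospho,
      covariateEffectSds = covariateEffectSds,
      nChromosomes = as.integer(nChromosomes),
      colocalizationBlockSize = as.integer(colocalizationBlockSize),
      fracColocalized = fracColocalized,
      fracPhosphoRegulatory = fracPhosphoRegulatory,
      phosphoBeta = phosphoBeta,
      missingRateProtein = missingRateProtein,
      missingRatePhospho = missingRatePhospho, seed = as.integer(seed))
}

#' Aligned multi-omics cohort
#'
#' Carrier of the matched omics layers used throughout the analysis. All
#' assay matrices are features x samples and share the sample axis; CNV
#' values are discretized GISTIC scores in \{-2, -1, 0, 1, 2\}. Phosphosite
#' rows are identified as `<gene>_S<position>` and mapped to their parent
#' protein through `phosphoMap`.
#'
#' @slot cnv integer gene x sample matrix of GISTIC scores.
#' @slot mrna,protein numeric gene x sample matrices (log scale, may contain
#'   `NA`).
#' @slot phospho numeric site x sample matrix (log scale, may contain `NA`).
#' @slot phosphoMap data.frame with columns `site`, `gene`, `position`.
#' @slot covariates data.frame with one row per sample: `cancer_type`,
#'   `batch`, `technology` (factors), `age` (numeric), `gender` (factor).
#' @aliases OmicsCohort-class
#' @exportClass OmicsCohort
setClass("OmicsCohort", representation(
  cnv = "matrix", mrna = "matrix", protein = "matrix", phospho = "matrix",
  phosphoMap = "data.frame", covariates = "data.frame"
))

setValidity("OmicsCohort", function(object) {
  msg <- character()
  smp <- colnames(object@cnv)
  for (nm in c("mrna", "protein", "phospho")) {
    m <- slot(object, nm)
    if (ncol(m) && !identical(colnames(m), smp))
      msg <- c(msg, paste0("sample axis of '", nm, "' differs from 'cnv'"))
  }
  if (nrow(object@covariates) != length(smp))
    msg <- c(msg, "covariates must have one row per sample")
  vals <- object@cnv[!is.na(object@cnv)]
  if (length(vals) && !all(vals %in% GISTIC_LEVELS))
    msg <- c(msg, "cnv values must be GISTIC levels -2..2")
  if (nrow(object@phospho) &&
      !all(object@phosphoMap$site %in% rownames(object@phospho)))
    msg <- c(msg, "phosphoMap sites absent from the phospho matrix")
  req <- c("cancer_type", "batch", "technology", "age", "gender")
  if (!all(req %in% colnames(object@covariates)))
    msg <- c(msg, paste0("covariates must contain: ",
                         paste(req, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsCohort
#'
#' @param cnv,mrna,protein gene x sample matrices on a shared sample axis.
#' @param phospho optional site x sample matrix.
#' @param phosphoMap data.frame (`site`, `gene`, `position`) for `phospho`.
#' @param covariates per-sample covariate data.frame.
#' @return An [OmicsCohort-class] object.
#' @export
omicsCohort <- function(cnv, mrna, protein,
                        phospho = matrix(numeric(), 0, ncol(cnv),
                                         dimnames = list(NULL, colnames(cnv))),
                        phosphoMap = data.frame(site = character(),
                                                gene = character(),
                                                position = integer()),
                        covariates) {
  storage.mode(cnv) <- "integer"
  new("OmicsCohort", cnv = cnv, mrna = mrna, protein = protein,
      phospho = phospho, phosphoMap = phosphoMap, covariates = covariates)
}

#' Ground truth of a synthetic cohort
#'
#' @slot classes named character vector: per-gene true attenuation class
#'   (`non_attenuated`, `low_attenuated`, `high_attenuated`).
#' @slot edges data.frame of true controlling edges: `controller`,
#'   `controlled`, `buffering`, `class`.
#' @slot complexes named list of character vectors (complex membership).
#' @slot geneMap data.frame: `gene`, `chromosome`, `position`, `block`.
#' @slot phosphoRegulators data.frame: `site`, `controller`, `controlled`,
#'   `beta`.
#' @slot passengers data.frame of colocalized passenger pairs: `passenger`,
#'   `controlled`, `controller`.
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  classes = "character", edges = "data.frame", complexes = "list",
  geneMap = "data.frame", phosphoRegulators = "data.frame",
  passengers = "data.frame"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(object@classes %in% c("non_attenuated", "low_attenuated",
                                 "high_attenuated")))
    msg <- c(msg, "unknown attenuation class label")
  att <- names(object@classes)[object@classes != "non_attenuated"]
  if (!all(att %in% object@edges$controlled))
    msg <- c(msg, "every attenuated gene needs at least one controlling edge")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples x", object@nGenes,
      "genes;", object@nComplexes, "complexes\n")
  cat(sprintf("  attenuated: %.0f%% (high %.0f%%, b = %.2f / low b = %.2f)\n",
              100 * object@fracAttenuated,
              100 * object@fracHighAttenuated,
              object@bufferingHigh, object@bufferingLow))
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "OmicsCohort", function(object) {
  cat("OmicsCohort with", ncol(object@cnv), "samples\n")
  cat("  cnv:    ", nrow(object@cnv), "genes\n")
  cat("  mrna:   ", nrow(object@mrna), "genes\n")
  cat("  protein:", nrow(object@protein), "genes\n")
  cat("  phospho:", nrow(object@phospho), "sites\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@classes), "genes,",
      sum(object@classes != "non_attenuated"), "attenuated,",
      nrow(object@edges), "controlling edges,",
      nrow(object@phosphoRegulators), "regulatory phosphosites\n")
})

#' @name cohort-accessors
#' @title Accessors for OmicsCohort and GroundTruth
#' @param x an `OmicsCohort` or `GroundTruth` object.
#' @return The corresponding slot: a matrix, data.frame, list or character
#'   vector.
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("cnvMatrix", function(x) standardGeneric("cnvMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("mrnaMatrix", function(x) standardGeneric("mrnaMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("proteinMatrix", function(x) standardGeneric("proteinMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("phosphoMatrix", function(x) standardGeneric("phosphoMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("phosphoMap", function(x) standardGeneric("phosphoMap"))
#' @rdname cohort-accessors
#' @export
setGeneric("sampleCovariates", function(x) standardGeneric("sampleCovariates"))
#' @rdname cohort-accessors
#' @export
setGeneric("trueClasses", function(x) standardGeneric("trueClasses"))
#' @rdname cohort-accessors
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))
#' @rdname cohort-accessors
#' @export
setGeneric("complexSets", function(x) standardGeneric("complexSets"))
#' @rdname cohort-accessors
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))
#' @rdname cohort-accessors
#' @export
setGeneric("phosphoRegulators", function(x) standardGeneric("phosphoRegulators"))

#' @rdname cohort-accessors
setMethod("cnvMatrix", "OmicsCohort", function(x) x@cnv)
#' @rdname cohort-accessors
setMethod("mrnaMatrix", "OmicsCohort", function(x) x@mrna)
#' @rdname cohort-accessors
setMethod("proteinMatrix", "OmicsCohort", function(x) x@protein)
#' @rdname cohort-accessors
setMethod("phosphoMatrix", "OmicsCohort", function(x) x@phospho)
#' @rdname cohort-accessors
setMethod("phosphoMap", "OmicsCohort", function(x) x@phosphoMap)
#' @rdname cohort-accessors
setMethod("sampleCovariates", "OmicsCohort", function(x) x@covariates)
#' @rdname cohort-accessors
setMethod("trueClasses", "GroundTruth", function(x) x@classes)
#' @rdname cohort-accessors
setMethod("trueEdges", "GroundTruth", function(x) x@edges)
#' @rdname cohort-accessors
setMethod("complexSets", "GroundTruth", function(x) x@complexes)
#' @rdname cohort-accessors
setMethod("geneMap", "GroundTruth", function(x) x@geneMap)
#' @rdname cohort-accessors
setMethod("phosphoRegulators", "GroundTruth", function(x) x@phosphoRegulators)
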