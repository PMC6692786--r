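# Shared fixtures, built in code at test time.

smallConfig <- function(seed = 1L, ...) {
  args <- list(nSamples = 80L, nGenes = 300L, nComplexes = 30L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulationConfig, args)
}

residualize <- function(cohort) {
  cov <- sampleCovariates(cohort)
  omicsCohort(cnv = cnvMatrix(cohort),
              mrna = regressConfounders(mrnaMatrix(cohort), cov),
              protein = regressConfounders(proteinMatrix(cohort), cov),
              phospho = phosphoMatrix(cohort),
              phosphoMap = phosphoMap(cohort),
              covariates = cov)
}

# A no-covariate-effect, no-missingness cohort for closed-form checks.
cleanConfig <- function(seed = 1L, ...) {
  smallConfig(seed = seed,
              covariateEffectSds = c(cancer_type = 0, batch = 0,
                                     technology = 0, age = 0, gender = 0),
              missingRateProtein = 0, missingRatePhospho = 0, ...)
}

toyAtoms <- function(x, radius = 1.7, chain = "A", resno = seq_len(nrow(x))) {
  data.frame(chain = chain, resno = resno, resid = "ALA", elety = "CA",
             x = x[, 1], y = x[, 2], z = x[, 3], radius = radius,
             stringsAsFactors = FALSE)
}
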