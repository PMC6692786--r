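# ProteoBuffer

Tumour genomes accumulate copy-number alterations (CNAs), yet a large part
of the proteome barely moves when gene dosage changes: subunits of protein
complexes are translated in excess and degraded when they fail to find
their binding partner, so the mRNA follows the DNA while the protein
follows the complex. `ProteoBuffer` implements, as a tested R package, the
statistical machinery for studying this interaction-mediated control of
protein abundance from matched multi-omics cohorts:

* **Attenuation analysis.** For every gene *i* with discretized GISTIC
  copy-number scores (−2…2), mRNA and protein profiles across samples, the
  attenuation potential

  > attenuation&nbsp;potentialᵢ = corr(CNVᵢ, mRNAᵢ) − corr(CNVᵢ, proteinᵢ)

  (Pearson correlations over pairwise-complete samples) measures how much
  of the dosage signal reaches the transcript but not the protein. A
  four-component univariate Gaussian mixture over the potentials, with a
  merging rule for the negative-mean component, classifies genes as
  non-, lowly or highly attenuated; hypergeometric tests score complex
  enrichment in the attenuated set.

* **Interaction-control screens.** For a candidate physical-interaction
  pair (X, Y), two nested ordinary-least-squares models for the protein
  level of Y are compared by a likelihood-ratio test:

  > null: P_y = β₀ + β₁T_y + (covariates) + ε
  > alternative: … + β₇G_x

  with LRT = 2[logLik(alt) − logLik(null)] = n·ln(RSS₀/RSS₁) referred to
  χ²(1), Benjamini–Hochberg FDR over the screen, intersection of the CNV
  (G_x) and mRNA (T_x) variants, Borda-rank deduplication of genomically
  colocalized controllers, and classification of proteins as controlling /
  controlled / both. A third screen adds a phosphosite of X on top of
  {T_y, G_x, P_x, covariates} to find phospho-modulated control.

* **Structural analysis.** Shrake–Rupley solvent-accessible surface areas
  (probe 1.4 Å), interface residues as those whose relative SASA changes
  between the bound complex and the isolated chain, structure QC filters,
  per-protein interface fractions and buried-area percentages, and their
  correlation with the screen statistics.

* **Validation on normal tissue and eQTL tables.** Harmonized gene×tissue
  panels with stratified controller–controlled correlations, and cis-eQTL
  LD blocks (connected components at r² > 0.8) whose GWAS-tagging fraction
  is stratified by attenuation class.

* **Synthetic cohorts with ground truth.** A generator that emulates the
  statistical structure of such cohorts — dosage propagation, buffering
  through complex membership, covariate effects, chromosomal
  co-amplification, phospho-dependent assembly, missingness — so every
  stage can be benchmarked against known truth without any download.

## Worked example

```r
library(ProteoBuffer)

cfg <- simulationConfig(nSamples = 120, nGenes = 600, nComplexes = 60,
                        seed = 42)
sim <- simulateCohort(cfg)
sim$truth
#> GroundTruth: 600 genes, 252 attenuated, 252 controlling edges,
#>   50 regulatory phosphosites

cov <- sampleCovariates(sim$cohort)
resid <- omicsCohort(cnv = cnvMatrix(sim$cohort),
                     mrna = regressConfounders(mrnaMatrix(sim$cohort), cov),
                     protein = regressConfounders(proteinMatrix(sim$cohort),
                                                  cov),
                     covariates = cov)

att <- computeAttenuation(resid, minPairs = 20)
head(att, 3)
#>    gene  rCnvMrna rCnvProtein nUsed potential
#> 1 g0001 0.8717914   0.6513446    97 0.2204468
#> 2 g0002 0.8991932   0.6651285    98 0.2340646
#> 3 g0003 0.8931164   0.6988439    96 0.1942725

cls <- classifyAttenuation(setNames(att$potential, att$gene), seed = 42)
table(cls$classes)
#>  non_attenuated  low_attenuated high_attenuated
#>             339             198              63
mean(as.character(cls$classes) == trueClasses(sim$truth)[att$gene])
#> [1] 0.985
```

The attenuation columns are the two dosage correlations, the number of
complete sample pairs used, and their difference (the potential); genes
with strong buffering sit in the upper mixture components. The screens
then recover the controlling edges:

```r
pairs   <- interactionPairs(sim$truth, seed = 42)
cnvRes  <- screenPairs(resid, pairs, variant = "cnv")
mrnaRes <- screenPairs(resid, pairs, variant = "mrna")
sig     <- intersectVariants(cnvRes, mrnaRes, threshold = 0.05)
final   <- deduplicateColocalized(sig, geneMap(sim$truth),
                                  cnvMatrix(sim$cohort))
attr(classifyControlStatus(final), "counts")
#> controlling  controlled        both
#>          62         254           2

head(final[, c("x", "y", "beta7", "lrtStat", "p", "fdr")], 3)
#>         x     y     beta7   lrtStat            p          fdr
#> 3   g0023 g0328 0.8400945 101.81367 6.099766e-24 2.357559e-21
#> 137 g0261 g0438 0.9856320  98.01114 4.160355e-23 1.071985e-20
#> 178 g0356 g0075 0.9855785  96.08852 1.098602e-22 2.066464e-20
```

`beta7` is the effect of the controller's copy number on the controlled
protein after discounting its own mRNA; `lrtStat` is n·ln(RSS₀/RSS₁). The
full chain — including the phospho screen, tissue panel and eQTL
stratification — is wrapped in `runPipeline()`, which writes stage TSVs
plus a checksummed JSON manifest, and `reportRun()`.

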