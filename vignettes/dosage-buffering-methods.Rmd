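---
title: "Methods: interaction-mediated buffering of gene dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction-mediated buffering of gene dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoBuffer)
```

## The model

Protein complex subunits are commonly produced in excess of what the
complex can absorb, and the unassembled surplus is degraded. When a
copy-number alteration raises or lowers a subunit's gene dosage, the mRNA
follows the DNA almost linearly, but the protein level is pinned to the
availability of its binding partners. Three linked analyses quantify this:

1. **Attenuation.** Per gene, the difference of Pearson correlations
   `corr(CNV, mRNA) − corr(CNV, protein)` over pairwise-complete samples.
   Under pure propagation the two correlations coincide and the potential
   is near zero (slightly positive in practice, because protein adds a
   measurement layer of noise); under buffering the protein correlation
   collapses and the potential approaches `b · corr(CNV, mRNA)`, where `b`
   is the buffering strength. Assumptions: dosage acts linearly on the log
   scale, and confounders (cancer type, batch, proteomics technology, age,
   gender) act additively and are removed beforehand by per-gene OLS
   residualization (`regressConfounders()`).

2. **Classification.** A four-component univariate Gaussian mixture with
   unequal variances is fitted to the potentials. Components are ordered
   by mean; any component with a negative mean (genes whose protein tracks
   dosage *better* than their mRNA — a measurement artifact, not
   biology) is merged with the lowest-nonnegative-mean component into the
   non-attenuated class; if no component has a negative mean the two
   lowest-mean components merge. The remaining two components become the
   low- and high-attenuated classes by ascending mean, and genes are
   assigned by maximum posterior responsibility. The mixture fit is
   delegated to `mclust::Mclust` (model `"V"`), whose
   hierarchical-agglomeration initialization is deterministic — the same
   potentials always give the same labels; we judged this preferable to a
   hand-rolled EM with randomized restarts, which adds a seed dependence
   without adding accuracy on one-dimensional data.

3. **Control screens.** For a directed candidate pair (X, Y) the null
   model `P_y ~ T_y + covariates` and the alternative with the added
   predictor (CNV of X, mRNA of X, or a phosphosite of X on top of
   `{T_y, G_x, P_x}`) are fitted by OLS **on the identical complete-case
   sample set** — the likelihood-ratio test is only valid when both models
   see the same data. With the Gaussian likelihood at the MLE variance
   RSS/n the statistic reduces to `n · ln(RSS₀/RSS₁)`, referred to χ²(1).
   Directionality comes from the genome: DNA copy number can drive protein
   levels but not vice versa, so a significant `β₇` for `G_x` supports
   X → Y control. The mRNA variant guards against CNV-specific artifacts;
   only pairs significant in both variants survive
   (`intersectVariants()`, strict FDR < 0.05 in each screen).

Because co-amplified neighbours of a true controller inherit its CNV
profile, several same-chromosome controllers of one controlled protein
are collapsed: controllers are Borda-ranked by aggregating the CNV-screen
and mRNA-screen p-value orderings (rank sum; ties by smaller CNV p, then
lexicographic id), the top controller is kept, and a further controller on
the same chromosome survives only when its CNV profile correlates below
0.5 with every retained one. The two p-value lists are our choice of
Borda input; any monotone pair of rankings of the same screens would do,
and the choice only matters for near-ties.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `minPairs` | 20 | minimum complete sample pairs per correlation; below this the gene is excluded with a reason rather than estimated noisily |
| coverage `minFraction` | 0.25 (proteins), 0.50 (phosphosites) | inclusive (≥) observed-fraction filter against a reference sample count |
| TMM trims | M 0.30, A 0.05 | the method's published defaults; the reference sample is the one whose upper quartile is closest to the mean upper quartile |
| log2-CPM prior count | 0.5 | voom-style expression scale after TMM |
| FDR threshold | 0.05, strict `<` | per screen, Benjamini–Hochberg |
| CNV profile correlation cap | 0.5 | colocalization exception in the deduplication |
| SASA probe radius | 1.4 Å | water probe |
| `nSpherePoints` | 960 | Shrake–Rupley sampling density (golden-spiral points) |
| interface tolerance | 1e-4 relative SASA | minimum change defining an interface residue |
| LD threshold | r² > 0.8, strict | blocks and GWAS proxies |
| tissue filter | expressed in ≥ 10 of 14 tissues, in both matrices | "expressed" = nonmissing and nonzero |
| mRNA band | [0, 0.4], inclusive | controls for transcriptional co-regulation in the tissue validation |

Normalization order differs by context: tumour matrices are quantile
normalized, coverage filtered, z-scored, then residualized; tissue panels
are z-scored then quantile normalized. Both orders are available in
`preprocessMatrix()`. Row z-scores use the population (divisor-n) standard
deviation. The phospho screen's covariate set is deliberately smaller
(batch, age, gender) than the protein screens' (plus cancer type and
technology), mirroring how such phospho cohorts are assembled.

## What the generator emulates — and what it does not

`simulateCohort()` draws GISTIC levels i.i.d. per colocalization block
(default probabilities 0.05/0.25/0.40/0.25/0.05 over −2…2; genes within a
block share one CNV profile), propagates them to mRNA with slope 1 and
Gaussian noise (s.d. 0.5), and sets protein to either its own mRNA
(non-attenuated) or the mixture `(1−b)·own mRNA + b·controller protein`
(attenuated), with the controller drawn from the same complex. Defaults
encode the reference study conditions: 368 samples, 2,000 genes, 42% of
genes attenuated, one quarter of those high class (`b = 0.8`), the rest
low class (`b = 0.4`) — the 3:1 low:high split follows the relative class
sizes such cohorts show. Covariate effects are additive on the log scale
with per-covariate effect s.d. 0.1–0.3; missingness is completely at
random (15% protein, 30% phosphosite). Regulatory phosphosites carry a
site-specific deviation `u` from their parent protein, and the controlled
protein gains `β₇·u` with `β₇ = 0.4`, so the nested-model coefficient of
the measured site equals `β₇` exactly.

The generator reproduces the *statistical* structure the analysis
assumes, not the data-generating physics: no read-level noise, no tumour
purity or clonality, no genome-coordinate realism beyond block
colocalization, no mechanism-specific missingness (real phospho
missingness is abundance-dependent), and buffering is exactly linear in
the controller's realized protein. Passing tests therefore demonstrate
that the implementation recovers truth *when the model holds*; they say
nothing about model misspecification on real cohorts.

Tissue panels give every gene an independent mRNA profile across 14
tissues with protein tracking mRNA (noise s.d. 0.3), controlled genes
mixing in the controller's mRNA at strength `b`. eQTL tables group
variants into latent LD blocks (within-block r² = 0.9, across-block
absent), with slope signs consistent per block and a GWAS-tagging
probability of 0.4 multiplied by a class factor (default 0.75 low / 0.5
high); tagging is realised half by direct catalogue membership, half
through an LD proxy.

## Numerical choices and degenerate inputs

* **LRT**: complete cases are computed on the union of all predictors of
  the larger model; an added predictor that is constant or lies in the
  column space of the base (QR rank test) is skipped with a reason, as is
  a pair with fewer complete cases than parameters + 3. The statistic is
  clamped at 0 against floating-point negatives.
* **χ²(1) approximation**: `p = P(χ²₁ > n·ln(RSS₀/RSS₁))` is exact only
  asymptotically. At n ≈ 300–370 the null p-values are uniform to about
  1–2% in Kolmogorov–Smirnov distance (slightly liberal in the 5% tail);
  BH control at FDR < 0.05 is unaffected in our checks. A
  Kolmogorov–Smirnov test on 10⁴ null screens sits at its own detection
  boundary for a deviation of this size, so its p-value fluctuates across
  seeds.
* **Mixture classification** requires ≥ 10·components observations and
  errors on constant potentials; attenuation records with constant CNV or
  fewer than `minPairs` pairs are excluded, not guessed.
* **Quantile normalization** with missing values maps observed values by
  rank fraction (limma's interpolating implementation); a single-row
  matrix degenerates to the row mean.
* **Isoform selection** breaks median ties by the lexicographically
  smallest isoform id; **complex deduplication** processes complexes in
  descending size and drops the later of any pair with Jaccard ≥ 0.9.
* **SASA**: golden-spiral point spheres are deterministic, and occlusion
  is exactly monotone at fixed points (an added atom can only remove
  accessible points). Interface *sets* are exactly invariant under
  rigid-body motion; the scalar buried fraction carries ~1% quadrature
  noise under rotation at 960 points, which is why the interface rule
  thresholds the relative-SASA *change* at 1e-4 rather than testing exact
  equality. Residues without a tabulated maximum ASA fall back to an
  absolute-area change criterion with a warning.
* **eQTL blocks**: "same slope sign" across tissues means the modal sign;
  genes exceeding 100 blocks are excluded before tagging; all LD
  thresholds are strict (r² > 0.8), so a proxy at exactly 0.8 does not
  tag.

## Problem sizes used in the checks

The test-suite and the acceptance script run the full analysis at the
reference cohort size (368 × 2,000, twenty seeds) for the classification
recovery, a 10,000-pair global-null screen plus twenty 50-edge cohorts
for calibration and power, and smaller cohorts (40–150 samples, 300–900
genes) for the tissue, eQTL and orchestration checks — sizes at which the
Monte-Carlo error of the recovered quantities is well below the margins
being asserted.

## Known limitations

* The screens establish statistical direction (DNA → protein), not
  mechanism; mutually exclusive complex membership can produce negative
  `β₇` that the model reports but does not interpret.
* Attenuation potentials inherit estimation noise ~ n^−1/2 per
  correlation; with fewer than ~100 samples the mixture components blur.
* The SASA implementation targets the package's pseudo-atom fixtures and
  modest PDB models; it is pure R and not tuned for thousands of large
  structures.
* Real normal-tissue panels have shared expression programs across
  tissues that the independent-profile generator does not emulate; the
  tissue validation on synthetic panels checks bookkeeping and power, not
  cross-tissue confounding.
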