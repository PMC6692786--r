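#' Filter eQTLs by cross-tissue slope-sign consistency
#'
#' Per variant-gene association, counts the tissues sharing the modal slope
#' sign and keeps associations consistent in at least `minTissues` tissues.
#'
#' @param eqtl data.frame with columns `variant`, `gene`, `tissue`, `slope`.
#' @param minTissues minimum consistent-tissue count (inclusive).
#' @return data.frame: `variant`, `gene`, `nTissuesConsistent`, for the
#'   surviving associations.
#' @export
filterTissueConsistency <- function(eqtl, minTissues = 3L) {
  key <- paste(eqtl$variant, eqtl$gene, sep = "\r")
  cnt <- vapply(split(sign(eqtl$slope), key), function(s)
    max(table(s[s != 0])), integer(1))
  first <- !duplicated(key)
  out <- data.frame(variant = eqtl$variant[first], gene = eqtl$gene[first],
                    nTissuesConsistent = unname(cnt[key[first]]),
                    stringsAsFactors = FALSE)
  out[out$nTissuesConsistent >= minTissues, , drop = FALSE]
}

#' Group a gene's eQTLs into LD blocks
#'
#' Blocks are the connected components of the graph whose vertices are the
#' gene's surviving eQTL variants and whose edges connect variants with LD
#' r-squared strictly above `r2Threshold`. Genes with more than
#' `maxBlocksPerGene` blocks are excluded entirely.
#'
#' @param eqtls output of [filterTissueConsistency()].
#' @param ld data.frame `variantA`, `variantB`, `r2` (treated symmetric).
#' @param r2Threshold LD threshold (strict `>`).
#' @param maxBlocksPerGene gene exclusion threshold.
#' @return data.frame: `gene`, `block`, `variant`, `nTissuesConsistent`;
#'   excluded genes in `attr(, "excludedGenes")`.
#' @export
buildBlocks <- function(eqtls, ld, r2Threshold = 0.8,
                        maxBlocksPerGene = 100L) {
  ld <- ld[ld$r2 > r2Threshold, , drop = FALSE]
  rows <- list(); excluded <- character()
  for (g in unique(eqtls$gene)) {
    sub <- eqtls[eqtls$gene == g, , drop = FALSE]
    vs <- sub$variant
    e <- ld[ld$variantA %in% vs & ld$variantB %in% vs, , drop = FALSE]
    gr <- igraph::graph_from_data_frame(
      e[, c("variantA", "variantB")], directed = FALSE,
      vertices = data.frame(name = vs))
    comp <- igraph::components(gr)$membership
    if (max(comp) > maxBlocksPerGene) { excluded <- c(excluded, g); next }
    rows[[g]] <- data.frame(gene = g, block = unname(comp[vs]),
                            variant = vs,
                            nTissuesConsistent = sub$nTissuesConsistent,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), block = integer(),
                      variant = character(), nTissuesConsistent = integer())
  rownames(out) <- NULL
  attr(out, "excludedGenes") <- excluded
  out
}

#' Flag LD blocks that tag GWAS-catalogue variants
#'
#' A block is GWAS-tagging when at least one member eQTL is itself a GWAS
#' variant or has an LD proxy (r-squared strictly above `r2Threshold`) in
#' the GWAS set.
#'
#' @param blocks output of [buildBlocks()].
#' @param ld LD table (`variantA`, `variantB`, `r2`; treated symmetric).
#' @param gwasVariants character vector of catalogue variants.
#' @param r2Threshold proxy threshold (strict `>`).
#' @return One row per (gene, block): `gene`, `block`, `nVariants`,
#'   `minTissuesConsistent`, `gwasTagging`.
#' @export
tagBlocks <- function(blocks, ld, gwasVariants, r2Threshold = 0.8) {
  ld <- ld[ld$r2 > r2Threshold, , drop = FALSE]
  proxied <- unique(c(ld$variantA[ld$variantB %in% gwasVariants],
                      ld$variantB[ld$variantA %in% gwasVariants]))
  tagging <- unique(c(gwasVariants, proxied))
  key <- paste(blocks$gene, blocks$block, sep = "\r")
  rows <- lapply(split(seq_len(nrow(blocks)), key), function(ix)
    data.frame(gene = blocks$gene[ix[1]], block = blocks$block[ix[1]],
               nVariants = length(ix),
               minTissuesConsistent = min(blocks$nTissuesConsistent[ix]),
               gwasTagging = any(blocks$variant[ix] %in% tagging),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' GWAS-tagging fraction of eQTL blocks by attenuation class
#'
#' For each cumulative tissue-count stratum (blocks whose eQTLs replicate
#' in at least that many tissues) and attenuation class, reports the
#' fraction of GWAS-tagging blocks among genes passing the CNV-mRNA
#' correlation filter and the optional complex-membership restriction.
#'
#' @param taggedBlocks output of [tagBlocks()].
#' @param classes named character/factor of attenuation classes per gene.
#' @param tissueStrata integer vector of cumulative minimum tissue counts.
#' @param attenuation optional data.frame with `gene` and `rCnvMrna`
#'   (from [computeAttenuation()]) for the correlation filter.
#' @param cnvMrnaRMin minimum CNV-mRNA Pearson r (strict `>`).
#' @param subsetGenes optional character vector restricting the genes (e.g.
#'   members of large complexes).
#' @return data.frame: `stratum` (min tissues), `class`, `nGenes`,
#'   `nBlocks`, `nTagged`, `fraction` (`NA` for empty strata).
#' @export
taggingFractionByClass <- function(taggedBlocks, classes,
                                   tissueStrata = c(3L, 5L, 7L, 9L),
                                   attenuation = NULL, cnvMrnaRMin = 0.3,
                                   subsetGenes = NULL) {
  tb <- taggedBlocks
  tb <- tb[tb$gene %in% names(classes), , drop = FALSE]
  if (!is.null(attenuation)) {
    pass <- attenuation$gene[!is.na(attenuation$rCnvMrna) &
                               attenuation$rCnvMrna > cnvMrnaRMin]
    tb <- tb[tb$gene %in% pass, , drop = FALSE]
  }
  if (!is.null(subsetGenes))
    tb <- tb[tb$gene %in% subsetGenes, , drop = FALSE]
  tb$class <- as.character(classes[tb$gene])
  levs <- c("non_attenuated", "low_attenuated", "high_attenuated")
  rows <- list()
  for (st in sort(tissueStrata)) {
    sub <- tb[tb$minTissuesConsistent >= st, , drop = FALSE]
    for (cl in levs) {
      s <- sub[sub$class == cl, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, class = cl, nGenes = length(unique(s$gene)),
        nBlocks = nrow(s), nTagged = sum(s$gwasTagging),
        fraction = if (nrow(s)) mean(s$gwasTagging) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
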