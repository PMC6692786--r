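#' Per-gene attenuation potential
#'
#' For every gene measured in the CNV, mRNA and protein layers, computes
#' the Pearson correlation of CNV with mRNA and of CNV with protein over
#' pairwise-complete samples, and the attenuation potential
#' `corr(CNV, mRNA) - corr(CNV, protein)`. A large potential flags genes
#' whose copy-number changes reach the transcript but are buffered at the
#' protein level.
#'
#' @param cohort an [OmicsCohort-class] (typically after confounder
#'   regression of the mRNA and protein layers).
#' @param minPairs minimum complete observations per correlation.
#' @return data.frame with columns `gene`, `rCnvMrna`, `rCnvProtein`,
#'   `nUsed`, `potential`. Genes excluded (too few pairs, constant CNV) are
#'   reported in `attr(, "excluded")` with a reason.
#' @export
computeAttenuation <- function(cohort, minPairs = 20L) {
  genes <- Reduce(intersect, list(rownames(cnvMatrix(cohort)),
                                  rownames(mrnaMatrix(cohort)),
                                  rownames(proteinMatrix(cohort))))
  cnv <- cnvMatrix(cohort)[genes, , drop = FALSE]
  mrna <- mrnaMatrix(cohort)[genes, , drop = FALSE]
  prot <- proteinMatrix(cohort)[genes, , drop = FALSE]
  rec <- vector("list", length(genes)); exc <- list()
  for (i in seq_along(genes)) {
    g <- cnv[i, ]; t <- mrna[i, ]; p <- prot[i, ]
    okM <- !is.na(g) & !is.na(t); okP <- !is.na(g) & !is.na(p)
    nUsed <- min(sum(okM), sum(okP))
    if (nUsed < minPairs) {
      exc[[length(exc) + 1L]] <- data.frame(gene = genes[i],
                                            reason = "too_few_pairs")
      next
    }
    if (sd(g[okM]) == 0 || sd(g[okP]) == 0) {
      exc[[length(exc) + 1L]] <- data.frame(gene = genes[i],
                                            reason = "constant_cnv")
      next
    }
    r1 <- cor(g[okM], t[okM]); r2 <- cor(g[okP], p[okP])
    rec[[i]] <- data.frame(gene = genes[i], rCnvMrna = r1, rCnvProtein = r2,
                           nUsed = nUsed, potential = r1 - r2,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rec)
  if (is.null(out))
    out <- data.frame(gene = character(), rCnvMrna = numeric(),
                      rCnvProtein = numeric(), nUsed = integer(),
                      potential = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(exc)) do.call(rbind, exc) else
    data.frame(gene = character(), reason = character())
  out
}

#' Classify genes into attenuation classes with a Gaussian mixture
#'
#' Fits a four-component univariate Gaussian mixture (unequal variances) to
#' the attenuation potentials and merges components into three classes:
#' components with negative mean join the lowest-nonnegative-mean component
#' as `non_attenuated` (if no component has a negative mean, the two
#' lowest-mean components merge); the remaining components become
#' `low_attenuated` and `high_attenuated` by ascending mean. Genes are
#' assigned by maximum posterior responsibility.
#'
#' @importFrom mclust Mclust mclustBIC
#' @param potentials named numeric vector of attenuation potentials.
#' @param nComponents mixture components before merging.
#' @param seed RNG seed (the hierarchical initialization is deterministic;
#'   the seed only guards optional randomized restarts inside mclust).
#' @return list with `classes` (named factor with levels `non_attenuated`,
#'   `low_attenuated`, `high_attenuated`), `componentMeans`,
#'   `componentClass` (component -> class map) and `model` (the mclust fit).
#' @export
classifyAttenuation <- function(potentials, nComponents = 4L, seed = 1L) {
  potentials <- potentials[!is.na(potentials)]
  if (length(potentials) < 10L * nComponents)
    stop("need at least ", 10L * nComponents, " potentials to fit ",
         nComponents, " components")
  if (sd(potentials) == 0)
    stop("attenuation potentials are constant; mixture model is degenerate")
  set.seed(seed)
  fit <- Mclust(as.numeric(potentials), G = nComponents,
                modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit did not converge")
  mu <- fit$parameters$mean
  ord <- order(mu)
  neg <- which(mu < 0)
  mergeSet <- if (length(neg)) {
    lowestNonneg <- ord[!(ord %in% neg)][1]
    c(neg, lowestNonneg)
  } else ord[1:2]
  remaining <- ord[!(ord %in% mergeSet)]
  lab <- setNames(rep("non_attenuated", nComponents), seq_len(nComponents))
  higher <- c("low_attenuated", "high_attenuated")
  if (length(remaining))
    lab[as.character(remaining)] <-
      rev(rev(higher)[seq_along(remaining)])   # ascending mean -> low, high
  classes <- factor(lab[as.character(fit$classification)],
                    levels = c("non_attenuated", "low_attenuated",
                               "high_attenuated"))
  names(classes) <- names(potentials)
  list(classes = classes, componentMeans = mu,
       componentClass = lab, model = fit)
}

#' Hypergeometric enrichment of complexes in the attenuated gene set
#'
#' Complexes are deduplicated with a greedy Jaccard filter (processed in
#' descending size; a later complex overlapping a kept one at Jaccard >= 0.9
#' is dropped) and restricted to complexes with more than `minSize`
#' members. For each surviving complex, a one-sided upper-tail
#' hypergeometric p-value for the overlap with the attenuated set is
#' computed and adjusted by Benjamini-Hochberg.
#'
#' @param attenuated character vector of attenuated genes.
#' @param complexes named list of complex membership vectors.
#' @param universe character vector of all tested genes.
#' @param jaccardMax Jaccard index at or above which a duplicate is dropped.
#' @param minSize complexes must have strictly more members than this.
#' @return data.frame: `complex`, `size`, `overlap`, `p`, `fdr`.
#' @export
enrichComplexes <- function(attenuated, complexes, universe,
                            jaccardMax = 0.9, minSize = 5L) {
  if (!length(universe)) stop("empty gene universe")
  complexes <- complexes[vapply(complexes, length, 1L) > minSize]
  complexes <- complexes[order(-vapply(complexes, length, 1L),
                               names(complexes))]
  kept <- list()
  for (nm in names(complexes)) {
    s <- complexes[[nm]]
    dup <- any(vapply(kept, function(k)
      length(intersect(k, s)) / length(union(k, s)) >= jaccardMax,
      logical(1)))
    if (!dup) kept[[nm]] <- s
  }
  att <- intersect(attenuated, universe)
  rows <- lapply(names(kept), function(nm) {
    inU <- intersect(kept[[nm]], universe)
    ov <- length(intersect(inU, att))
    p <- phyper(ov - 1L, length(att), length(universe) - length(att),
                length(inU), lower.tail = FALSE)
    data.frame(complex = nm, size = length(inU), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(complex = character(), size = integer(),
                      overlap = integer(), p = numeric(), fdr = numeric()))
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' ROC curve for predicting complex co-membership from profile correlation
#'
#' Sweeps the score threshold and reports the receiver operating
#' characteristic plus the trapezoid AUC; used to check that protein
#' abundance correlations predict protein-protein interaction pairs better
#' than mRNA correlations.
#'
#' @param labels logical (TRUE = pair in the same complex).
#' @param scores numeric score per pair (e.g. Pearson r of profiles).
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
rocPairPrediction <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  ok <- !is.na(labels) & !is.na(scores)
  labels <- as.logical(labels)[ok]; scores <- scores[ok]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("ROC needs both positive and negative pairs")
  ord <- order(scores, decreasing = TRUE)
  labs <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(labs); fp <- cumsum(!labs)
  last <- !duplicated(sc, fromLast = TRUE)   # one point per threshold
  tpr <- c(0, tp[last] / nPos); fpr <- c(0, fp[last] / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, sc[last]), auc = auc)
}

#' Pairwise Wilcoxon rank-sum comparisons between classes
#'
#' Two-sided rank-sum tests for every pair of class levels; exact
#' enumeration when both groups have at most `exactMax` observations and no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param values numeric vector (e.g. attenuation potential per gene).
#' @param labels class label per value.
#' @param exactMax maximum group size for the exact test.
#' @return data.frame: `group1`, `group2`, `n1`, `n2`, `statistic`, `p`.
#' @export
compareGroups <- function(values, labels, exactMax = 25L) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- factor(labels[ok])
  lev <- levels(labels)
  if (any(table(labels) < 2)) stop("each compared group needs >= 2 values")
  pairs <- utils::combn(lev, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- values[labels == pr[1]]; b <- values[labels == pr[2]]
    exact <- length(a) <= exactMax && length(b) <= exactMax &&
      !anyDuplicated(c(a, b))
    wt <- wilcox.test(a, b, exact = exact, correct = TRUE)
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(a),
               n2 = length(b), statistic = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
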