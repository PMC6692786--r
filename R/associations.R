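## Covariate designs used by the screens (dummy-coded, with intercept).
covariateDesign <- function(covariates, vars) {
  keep <- vars[vapply(vars, function(v)
    length(unique(covariates[[v]])) > 1, logical(1))]
  if (!length(keep))
    return(matrix(1, nrow(covariates), 1,
                  dimnames = list(rownames(covariates), "(Intercept)")))
  model.matrix(stats::reformulate(keep), covariates)
}

#' Likelihood-ratio test between nested ordinary-least-squares models
#'
#' Fits the null model `y ~ base` and the alternative `y ~ base + added` on
#' the identical complete-case sample set, computes the Gaussian
#' log-likelihood with maximum-likelihood variance (RSS/n), so the LRT
#' statistic reduces to `n * ln(RSS_null / RSS_alt)`, and compares it to a
#' chi-squared distribution with one degree of freedom.
#'
#' @param y numeric response vector.
#' @param base numeric matrix of null-model predictors (including the
#'   intercept column).
#' @param added numeric vector: the single predictor the alternative adds.
#' @return list with `beta7` (coefficient of `added`), `lrtStat`, `p`,
#'   `nUsed`; or `NULL` with attribute-free skip via a `skip` element when
#'   the added predictor is constant or collinear with the base, or too few
#'   complete cases remain.
#' @export
fitNestedLrt <- function(y, base, added) {
  ok <- !is.na(y) & !is.na(added) & rowSums(is.na(base)) == 0
  n <- sum(ok)
  if (n <= ncol(base) + 3L)
    return(list(skip = "too_few_complete_cases", nUsed = n))
  y <- y[ok]; X0 <- base[ok, , drop = FALSE]; g <- added[ok]
  if (sd(g) == 0)
    return(list(skip = "added_predictor_constant", nUsed = n))
  q0 <- qr(X0)
  X0 <- X0[, q0$pivot[seq_len(q0$rank)], drop = FALSE]
  X1 <- cbind(X0, .added = g)
  q1 <- qr(X1)
  if (q1$rank <= ncol(X0))
    return(list(skip = "added_predictor_collinear", nUsed = n))
  rss0 <- sum(qr.resid(q0, y)^2)
  f1 <- stats::lm.fit(X1, y)
  rss1 <- sum(f1$residuals^2)
  lrt <- max(0, n * log(rss0 / rss1))
  list(beta7 = unname(f1$coefficients[".added"]), lrtStat = lrt,
       p = pchisq(lrt, df = 1, lower.tail = FALSE), nUsed = n)
}

#' Screen candidate protein pairs for interaction-mediated control
#'
#' For each directed candidate pair (X, Y), tests whether the CNV of X
#' (`variant = "cnv"`) or the mRNA of X (`variant = "mrna"`) predicts the
#' protein level of Y beyond Y's own mRNA and the sample covariates
#' (cancer type, batch, technology, age, gender), using [fitNestedLrt()].
#' P-values are Benjamini-Hochberg adjusted over all tested pairs in the
#' screen.
#'
#' @param cohort an [OmicsCohort-class].
#' @param pairs data.frame with columns `x` (candidate controller) and `y`
#'   (candidate controlled); homodimers (`x == y`) are dropped.
#' @param variant `"cnv"` or `"mrna"`: the layer of X added as predictor.
#' @return data.frame of association results (`x`, `y`, `variant`, `beta7`,
#'   `lrtStat`, `p`, `fdr`, `nUsed`), sorted as the input; skipped pairs in
#'   `attr(, "skipped")` with reasons.
#' @export
screenPairs <- function(cohort, pairs, variant = c("cnv", "mrna")) {
  variant <- match.arg(variant)
  pairs <- pairs[pairs$x != pairs$y, , drop = FALSE]
  D <- covariateDesign(sampleCovariates(cohort),
                       c("cancer_type", "batch", "technology", "age",
                         "gender"))
  prot <- proteinMatrix(cohort); mrna <- mrnaMatrix(cohort)
  xmat <- if (variant == "cnv") cnvMatrix(cohort) else mrna
  res <- vector("list", nrow(pairs)); skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    x <- pairs$x[i]; y <- pairs$y[i]
    if (!(x %in% rownames(xmat)) || !(y %in% rownames(prot)) ||
        !(y %in% rownames(mrna))) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(x = x, y = y, reason = "gene_not_measured")
      next
    }
    fit <- fitNestedLrt(prot[y, ], cbind(D, Ty = mrna[y, ]), xmat[x, ])
    if (!is.null(fit$skip)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(x = x, y = y, reason = fit$skip)
      next
    }
    res[[i]] <- data.frame(x = x, y = y, variant = variant,
                           beta7 = fit$beta7, lrtStat = fit$lrtStat,
                           p = fit$p, nUsed = fit$nUsed,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(x = character(), y = character(), variant = character(),
                      beta7 = numeric(), lrtStat = numeric(), p = numeric(),
                      nUsed = integer(), stringsAsFactors = FALSE)
  out$fdr <- benjaminiHochberg(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(x = character(), y = character(), reason = character())
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
benjaminiHochberg <- function(p) p.adjust(p, method = "BH")

#' Intersect CNV- and mRNA-variant screen results
#'
#' Keeps pairs significant (FDR strictly below `threshold`) in both the CNV
#' screen and the mRNA screen.
#'
#' @param cnvResults,mrnaResults outputs of [screenPairs()].
#' @param threshold FDR cutoff (strict `<`).
#' @return The CNV-screen rows of the intersection, with the mRNA screen's
#'   `mrnaP` and `mrnaFdr` columns appended.
#' @export
intersectVariants <- function(cnvResults, mrnaResults, threshold = 0.05) {
  m <- merge(cnvResults[cnvResults$fdr < threshold, ],
             mrnaResults[mrnaResults$fdr < threshold,
                         c("x", "y", "p", "fdr")],
             by = c("x", "y"), suffixes = c("", ".mrna"))
  names(m)[names(m) == "p.mrna"] <- "mrnaP"
  names(m)[names(m) == "fdr.mrna"] <- "mrnaFdr"
  m[order(m$p), ]
}

#' Deduplicate genomically colocalized controllers
#'
#' Copy-number changes co-amplify neighbouring genes, so several
#' controllers on one chromosome can spuriously associate with the same
#' controlled protein. Per controlled gene and chromosome, controllers are
#' Borda-ranked by aggregating the CNV-screen and mRNA-screen p-value
#' orderings (rank sum; ties by smaller CNV p, then gene id); the top
#' controller is kept and a further same-chromosome controller is retained
#' only when its CNV profile correlates below `corMax` with every retained
#' one.
#'
#' @param pairs output of [intersectVariants()] (needs `x`, `y`, `p`,
#'   `mrnaP`).
#' @param geneMap data.frame with columns `gene` and `chromosome`.
#' @param cnv gene x sample CNV matrix for profile correlations.
#' @param corMax Pearson correlation threshold (strict `<` keeps).
#' @return The filtered pair data.frame.
#' @export
deduplicateColocalized <- function(pairs, geneMap, cnv, corMax = 0.5) {
  if (!nrow(pairs)) return(pairs)
  chromOf <- setNames(geneMap$chromosome, geneMap$gene)
  miss <- setdiff(unique(pairs$x), names(chromOf))
  if (length(miss))
    warning("no chromosome for controller(s): ",
            paste(miss, collapse = ", "), "; passed through unfiltered")
  keepRow <- logical(nrow(pairs))
  for (y in unique(pairs$y)) {
    idx <- which(pairs$y == y)
    chr <- chromOf[pairs$x[idx]]
    keepRow[idx[is.na(chr)]] <- TRUE
    for (cc in unique(chr[!is.na(chr)])) {
      grp <- idx[!is.na(chr) & chr == cc]
      if (length(grp) == 1L) { keepRow[grp] <- TRUE; next }
      borda <- rank(pairs$p[grp]) + rank(pairs$mrnaP[grp])
      ord <- grp[order(borda, pairs$p[grp], pairs$x[grp])]
      kept <- ord[1]
      for (cand in ord[-1]) {
        r <- vapply(kept, function(k)
          cor(cnv[pairs$x[cand], ], cnv[pairs$x[k], ],
              use = "pairwise.complete.obs"), numeric(1))
        if (all(abs(r) < corMax, na.rm = TRUE)) kept <- c(kept, cand)
      }
      keepRow[kept] <- TRUE
    }
  }
  pairs[keepRow, , drop = FALSE]
}

#' Classify proteins by control status
#'
#' A protein is `controlling` when it appears as X in at least one final
#' pair, `controlled` when it appears as Y, and `both` when it does both.
#'
#' @param pairs data.frame with `x` and `y` columns (final significant
#'   pairs).
#' @return data.frame: `gene`, `status`; counts in `attr(, "counts")`.
#' @export
classifyControlStatus <- function(pairs) {
  if (!nrow(pairs)) stop("empty pair set")
  xs <- unique(pairs$x); ys <- unique(pairs$y)
  genes <- sort(union(xs, ys))
  status <- ifelse(genes %in% xs & genes %in% ys, "both",
                   ifelse(genes %in% xs, "controlling", "controlled"))
  out <- data.frame(gene = genes, status = status, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(controlling = sum(status == "controlling"),
                           controlled = sum(status == "controlled"),
                           both = sum(status == "both"))
  out
}

#' Screen phosphosites for modulation of protein-protein control
#'
#' For a candidate pair (X, Y) and each phosphosite Xp of X, tests whether
#' Xp predicts the protein level of Y beyond Y's mRNA, the CNV and protein
#' levels of X, and the covariates batch, age and gender. Significant
#' phospho associations are finally restricted to pairs (X, Y) in the
#' protein-level significant set, so the phosphosite evidence stays
#' directional.
#'
#' @param cohort an [OmicsCohort-class] with a phospho layer.
#' @param pairs candidate pair data.frame (`x`, `y`).
#' @param proteinPairs data.frame of protein-level significant pairs
#'   (`x`, `y`), e.g. after [deduplicateColocalized()]; `NULL` skips the
#'   overlap step.
#' @param threshold FDR cutoff for the final set (strict `<`).
#' @return list with `results` (all tested site-pair associations with
#'   `fdr`) and `final` (significant associations whose (X, Y) is
#'   protein-significant).
#' @export
screenPhospho <- function(cohort, pairs, proteinPairs = NULL,
                          threshold = 0.05) {
  pairs <- pairs[pairs$x != pairs$y, , drop = FALSE]
  D <- covariateDesign(sampleCovariates(cohort),
                       c("batch", "age", "gender"))
  prot <- proteinMatrix(cohort); mrna <- mrnaMatrix(cohort)
  cnv <- cnvMatrix(cohort); pho <- phosphoMatrix(cohort)
  pmap <- phosphoMap(cohort)
  res <- list(); skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    x <- pairs$x[i]; y <- pairs$y[i]
    sitesX <- pmap$site[pmap$gene == x]
    if (!length(sitesX)) next
    if (!(x %in% rownames(prot)) || !(x %in% rownames(cnv)) ||
        !(y %in% rownames(prot)) || !(y %in% rownames(mrna))) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(site = sitesX, x = x, y = y, reason = "gene_not_measured")
      next
    }
    base <- cbind(D, Ty = mrna[y, ], Gx = cnv[x, ], Px = prot[x, ])
    for (s in sitesX) {
      fit <- fitNestedLrt(prot[y, ], base, pho[s, ])
      if (!is.null(fit$skip)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(site = s, x = x, y = y, reason = fit$skip)
        next
      }
      res[[length(res) + 1L]] <- data.frame(
        site = s, x = x, y = y, variant = "phospho", beta7 = fit$beta7,
        lrtStat = fit$lrtStat, p = fit$p, nUsed = fit$nUsed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(site = character(), x = character(), y = character(),
                      variant = character(), beta7 = numeric(),
                      lrtStat = numeric(), p = numeric(), nUsed = integer(),
                      stringsAsFactors = FALSE)
  out$fdr <- benjaminiHochberg(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(site = character(), x = character(), y = character(),
               reason = character())
  final <- out[out$fdr < threshold, , drop = FALSE]
  if (!is.null(proteinPairs))
    final <- final[paste(final$x, final$y) %in%
                     paste(proteinPairs$x, proteinPairs$y), , drop = FALSE]
  list(results = out, final = final)
}
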