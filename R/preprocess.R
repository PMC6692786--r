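#' Merge replicate columns of an abundance matrix
#'
#' Protein replicate runs are combined by the mean, phosphopeptides mapping
#' to the same site by the median; missing values are ignored unless a whole
#' replicate group is missing.
#'
#' @param x numeric matrix, features x columns.
#' @param replicateMap character/factor of length `ncol(x)` giving the
#'   sample each column belongs to (must partition the columns).
#' @param method `"mean"` or `"median"`.
#' @return matrix with one column per sample, in first-appearance order.
#' @export
mergeReplicates <- function(x, replicateMap, method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(replicateMap) != ncol(x))
    stop("replicateMap must have one entry per column")
  groups <- unique(as.character(replicateMap))
  fun <- if (method == "mean") mean else median
  out <- vapply(groups, function(g) {
    cols <- which(replicateMap == g)
    if (!length(cols)) stop("empty replicate group: ", g)
    apply(x[, cols, drop = FALSE], 1, function(v)
      if (all(is.na(v))) NA_real_ else fun(v, na.rm = TRUE))
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), groups))
  out
}

#' Collapse isoform rows to one row per gene
#'
#' Retains, per gene, the isoform with the highest median abundance across
#' samples; ties are broken by the lexicographically smallest isoform id.
#'
#' @param x numeric matrix with isoform rownames.
#' @param isoformToGene named character vector mapping isoform id to gene.
#' @return matrix with one row per gene (rownames are gene ids).
#' @export
selectIsoform <- function(x, isoformToGene) {
  if (!all(rownames(x) %in% names(isoformToGene)))
    stop("every isoform must map to a gene")
  med <- apply(x, 1, median, na.rm = TRUE)
  iso <- rownames(x)[order(isoformToGene[rownames(x)], -med,
                           rownames(x), method = "radix")]
  keep <- iso[!duplicated(isoformToGene[iso])]
  out <- x[keep, , drop = FALSE]
  rownames(out) <- unname(isoformToGene[keep])
  out[order(rownames(out)), , drop = FALSE]
}

#' Filter features by measurement coverage
#'
#' Keeps rows observed in at least `minFraction` of `referenceSampleCount`
#' samples (inclusive threshold).
#'
#' @param x numeric matrix with `NA` for missing entries.
#' @param minFraction minimum observed fraction in (0, 1].
#' @param referenceSampleCount denominator sample count; defaults to
#'   `ncol(x)`.
#' @return The filtered matrix.
#' @export
filterByCoverage <- function(x, minFraction, referenceSampleCount = ncol(x)) {
  stopifnot(minFraction > 0, minFraction <= 1)
  obs <- rowSums(!is.na(x))
  x[obs / referenceSampleCount >= minFraction, , drop = FALSE]
}

#' Filter and normalize an RNA-seq count matrix to log2-CPM
#'
#' Removes genes with mean counts-per-million below 1, computes
#' trimmed-mean-of-M-values (TMM) scaling factors and returns log2-CPM with
#' a 0.5 prior count (the standard voom-style expression scale).
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @param minMeanCpm mean-CPM filter threshold.
#' @param trimM,trimA TMM trim fractions for M- and A-values.
#' @return list with `logcpm` (matrix) and `normFactors` (per sample).
#' @export
normalizeCounts <- function(counts, minMeanCpm = 1, trimM = 0.3,
                            trimA = 0.05) {
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  libSize <- colSums(counts)
  if (any(libSize == 0)) stop("all-zero sample in count matrix")
  cpm0 <- t(t(counts) / libSize) * 1e6
  keep <- rowMeans(cpm0) >= minMeanCpm
  counts <- counts[keep, , drop = FALSE]
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM", logratioTrim = trimM,
                                sumTrim = trimA)
  logcpm <- edgeR::cpm(dge, log = TRUE, prior.count = 0.5)
  list(logcpm = logcpm, normFactors = dge$samples$norm.factors)
}

#' Quantile normalize the columns of a matrix
#'
#' Each column's sorted values are replaced by the mean of sorted values
#' across columns; missing entries are excluded from the quantile
#' computation (and mapped back by rank fraction) and stay missing.
#'
#' @param x numeric matrix with at least 2 columns.
#' @return The normalized matrix.
#' @export
quantileNormalize <- function(x) {
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 columns")
  if (nrow(x) == 1) {          # degenerate: every entry is the row mean
    x[] <- mean(x, na.rm = TRUE)
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Standardize matrix rows to z-scores
#'
#' Rows get mean 0 and population (n-divisor) s.d. 1 over their observed
#' entries. Constant rows (zero s.d.) cannot be standardized and are
#' dropped with a warning.
#'
#' @param x numeric matrix.
#' @return The standardized matrix, constant rows removed.
#' @export
zscoreRows <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- sqrt(rowMeans((x - mu)^2, na.rm = TRUE))
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    warning(sum(bad), " constant row(s) dropped: ",
            paste(head(rownames(x)[bad], 5), collapse = ", "))
    x <- x[!bad, , drop = FALSE]; mu <- mu[!bad]; sdv <- sdv[!bad]
  }
  (x - mu) / sdv
}

#' Regress confounding covariates out of each matrix row
#'
#' Fits, per feature, an ordinary-least-squares model of abundance on
#' dummy-coded cancer type, batch, technology, gender and numeric age, and
#' returns the residuals (missing entries stay missing). Aliased design
#' columns are dropped by the QR fit with a warning.
#'
#' @param x numeric matrix, features x samples.
#' @param covariates data.frame with one row per sample.
#' @param formula model formula over `covariates`.
#' @return Residual matrix with the dimensions and dimnames of `x`.
#' @export
regressConfounders <- function(x, covariates,
                               formula = ~ cancer_type + batch + technology +
                                 age + gender) {
  if (nrow(covariates) != ncol(x))
    stop("covariates must have one row per sample")
  if (anyNA(covariates)) stop("covariates must be complete for all samples")
  keep <- vapply(all.vars(formula), function(v)
    length(unique(covariates[[v]])) > 1, logical(1))
  if (!any(keep)) {                       # intercept-only model: centering
    return(x - rowMeans(x, na.rm = TRUE))
  }
  form <- stats::reformulate(all.vars(formula)[keep])
  D <- model.matrix(form, covariates)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("rank-deficient confounder design; dropping aliased columns: ",
            paste(colnames(D)[-qrD$pivot[seq_len(qrD$rank)]],
                  collapse = ", "))
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
  }
  res <- x
  complete <- !is.na(x)
  allObs <- rowSums(complete) == ncol(x)
  if (any(allObs)) {          # fast path: one multi-response QR fit
    fit <- stats::lm.fit(D, t(x[allObs, , drop = FALSE]))
    res[allObs, ] <- t(fit$residuals)
  }
  for (i in which(!allObs)) {
    obs <- complete[i, ]
    if (sum(obs) <= ncol(D)) { res[i, ] <- NA_real_; next }
    Do <- D[obs, , drop = FALSE]
    qi <- qr(Do)
    Do <- Do[, qi$pivot[seq_len(qi$rank)], drop = FALSE]
    res[i, obs] <- stats::lm.fit(Do, x[i, obs])$residuals
  }
  res
}

#' Run the default preprocessing chain on an abundance matrix
#'
#' merge replicates -> isoform selection -> quantile normalization ->
#' coverage filter -> z-score -> confounder regression, in the order used
#' for the tumour matrices; the tissue panels use z-score before quantile
#' normalization (`order = "zscore_first"`).
#'
#' @param x feature x column matrix.
#' @param covariates per-sample covariates (after replicate merging).
#' @param replicateMap optional column -> sample map.
#' @param isoformToGene optional isoform -> gene map.
#' @param minFraction coverage threshold (default 0.25 as for proteins
#'   measured in at least a quarter of samples).
#' @param referenceSampleCount coverage denominator.
#' @param order `"quantile_first"` (tumour) or `"zscore_first"` (tissue).
#' @return The processed matrix.
#' @export
preprocessMatrix <- function(x, covariates = NULL, replicateMap = NULL,
                             isoformToGene = NULL, minFraction = 0.25,
                             referenceSampleCount = NULL,
                             order = c("quantile_first", "zscore_first")) {
  order <- match.arg(order)
  if (!is.null(replicateMap)) x <- mergeReplicates(x, replicateMap, "mean")
  if (!is.null(isoformToGene)) x <- selectIsoform(x, isoformToGene)
  if (is.null(referenceSampleCount)) referenceSampleCount <- ncol(x)
  if (order == "quantile_first") {
    x <- quantileNormalize(x)
    x <- filterByCoverage(x, minFraction, referenceSampleCount)
    x <- zscoreRows(x)
  } else {
    x <- filterByCoverage(x, minFraction, referenceSampleCount)
    x <- zscoreRows(x)
    x <- quantileNormalize(x)
  }
  if (!is.null(covariates)) x <- regressConfounders(x, covariates)
  x
}
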