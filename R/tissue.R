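#' Harmonize normal-tissue mRNA and protein panels
#'
#' Averages sub-tissue columns into their parent tissue, intersects genes
#' and tissues between the mRNA and protein matrices, keeps genes expressed
#' (nonmissing and nonzero) in at least `minTissues` tissues in both
#' matrices, and then z-scores rows and quantile-normalizes columns (in
#' that order, as used for the tissue panels).
#'
#' @param mrna,protein gene x (sub)tissue matrices.
#' @param subtissueMap optional named character vector mapping sub-tissue
#'   column names to merged tissue names (unlisted columns keep their name).
#' @param minTissues minimum expressed-tissue count (inclusive) per matrix.
#' @return list of class `TissuePanel`: `mrna`, `protein`, `tissues`.
#' @export
harmonizePanel <- function(mrna, protein, subtissueMap = NULL,
                           minTissues = 10L) {
  mergeSub <- function(x) {
    if (is.null(subtissueMap)) return(x)
    tiss <- ifelse(colnames(x) %in% names(subtissueMap),
                   subtissueMap[colnames(x)], colnames(x))
    out <- vapply(unique(tiss), function(tt)
      rowMeans(x[, tiss == tt, drop = FALSE], na.rm = FALSE),
      numeric(nrow(x)))
    matrix(out, nrow = nrow(x), dimnames = list(rownames(x), unique(tiss)))
  }
  mrna <- mergeSub(mrna); protein <- mergeSub(protein)
  tissues <- intersect(colnames(mrna), colnames(protein))
  if (length(tissues) < 2) stop("fewer than 2 common tissues")
  genes <- intersect(rownames(mrna), rownames(protein))
  mrna <- mrna[genes, tissues, drop = FALSE]
  protein <- protein[genes, tissues, drop = FALSE]
  expressed <- function(x) rowSums(!is.na(x) & x != 0)
  keep <- expressed(mrna) >= minTissues & expressed(protein) >= minTissues
  mrna <- mrna[keep, , drop = FALSE]; protein <- protein[keep, , drop = FALSE]
  norm <- function(x) quantileNormalize(zscoreRows(x))
  structure(list(mrna = norm(mrna), protein = norm(protein),
                 tissues = tissues), class = "TissuePanel")
}

#' Per-pair tissue correlations stratified by association significance
#'
#' For each controlling-controlled candidate pair, computes across tissues
#' the Pearson correlations protein(X)-protein(Y), mRNA(X)-mRNA(Y) and
#' mRNA(Y)-protein(Y) (the controlled gene's own mRNA-protein coupling)
#' over complete tissue observations, optionally restricted to pairs whose
#' mRNA-mRNA correlation lies in `band` (inclusive endpoints, to control
#' for transcriptional co-regulation). Class strata are compared with
#' [compareGroups()].
#'
#' @param panel a `TissuePanel` from [harmonizePanel()].
#' @param pairs data.frame with `x`, `y` and a significance class column
#'   `class` (e.g. `nonsig`, `sig`, `highsig`).
#' @param band optional numeric (lo, hi) mRNA-correlation band filter.
#' @param minTissueObs minimum complete tissue observations per pair.
#' @return list with `correlations` (per-pair data.frame: `x`, `y`,
#'   `class`, `rProteinProtein`, `rMrnaMrna`, `rMrnaProtein`, `nTissues`)
#'   and `tests` (pairwise class comparisons for the protein-protein
#'   correlation), or `tests = NULL` with fewer than two classes.
#' @export
stratifiedPairCorrelations <- function(panel, pairs, band = NULL,
                                       minTissueObs = 3L) {
  mrna <- panel$mrna; protein <- panel$protein
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- pairs$x[i]; y <- pairs$y[i]
    if (!all(c(x, y) %in% rownames(mrna)) ||
        !all(c(x, y) %in% rownames(protein))) next
    okPP <- !is.na(protein[x, ]) & !is.na(protein[y, ])
    okMM <- !is.na(mrna[x, ]) & !is.na(mrna[y, ])
    okMP <- !is.na(mrna[y, ]) & !is.na(protein[y, ])
    if (min(sum(okPP), sum(okMM), sum(okMP)) < minTissueObs) next
    rows[[i]] <- data.frame(
      x = x, y = y, class = pairs$class[i],
      rProteinProtein = cor(protein[x, okPP], protein[y, okPP]),
      rMrnaMrna = cor(mrna[x, okMM], mrna[y, okMM]),
      rMrnaProtein = cor(mrna[y, okMP], protein[y, okMP]),
      nTissues = sum(okPP), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pair measurable in the panel")
  if (!is.null(band))
    out <- out[out$rMrnaMrna >= band[1] & out$rMrnaMrna <= band[2], ,
               drop = FALSE]
  rownames(out) <- NULL
  tests <- if (length(unique(out$class)) >= 2 &&
               all(table(out$class) >= 2))
    compareGroups(out$rProteinProtein, out$class) else NULL
  list(correlations = out, tests = tests)
}
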