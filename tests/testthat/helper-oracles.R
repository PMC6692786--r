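# Independent oracles, deliberately coded differently from the package.

# Step-up BH by the textbook recipe.
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# Exhaustive hypergeometric upper tail by enumerating draw compositions.
bruteHyperUpper <- function(overlap, nAtt, nUniverse, nComplex) {
  ks <- overlap:min(nAtt, nComplex)
  sum(choose(nAtt, ks) * choose(nUniverse - nAtt, nComplex - ks)) /
    choose(nUniverse, nComplex)
}

# Connected components by label propagation (no igraph).
bruteComponents <- function(vertices, edges) {
  lab <- seq_along(vertices)
  names(lab) <- vertices
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges$variantA[i]; b <- edges$variantB[i]
      if (!(a %in% vertices) || !(b %in% vertices)) next
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[c(a, b)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  as.integer(factor(lab, levels = unique(lab)))
}

# Nested-model LRT through lm() + logLik(), the classical route.
lmLrt <- function(y, base, added) {
  d0 <- data.frame(y = y, base)
  d1 <- data.frame(y = y, base, .added = added)
  ok <- stats::complete.cases(d1)
  m0 <- stats::lm(y ~ . - 1, d0[ok, , drop = FALSE])
  m1 <- stats::lm(y ~ . - 1, d1[ok, , drop = FALSE])
  as.numeric(2 * (stats::logLik(m1) - stats::logLik(m0)))
}
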