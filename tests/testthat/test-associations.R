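test_that("nested LRT: zero partial correlation gives zero statistic, and
           the statistic is never negative", {
  n <- 40
  base <- cbind(1, rnorm(n))
  ## construct an added predictor exactly orthogonal to y and the base
  set.seed(1)
  y <- rnorm(n)
  g0 <- rnorm(n)
  M <- cbind(base, y)
  g <- g0 - M %*% solve(crossprod(M), crossprod(M, g0))
  fit <- fitNestedLrt(y, base, as.numeric(g))
  expect_equal(fit$lrtStat, 0, tolerance = 1e-9)
  expect_equal(fit$p, 1, tolerance = 1e-6)
  for (i in 1:25) {
    y <- rnorm(n); g <- rnorm(n)
    f <- fitNestedLrt(y, base, g)
    expect_gte(f$lrtStat, 0)
  }
})

test_that("nested LRT equals the classical lm/logLik likelihood-ratio and
           n*ln(RSS0/RSS1) from independent code", {
  set.seed(2)
  for (i in 1:20) {
    n <- 100
    base <- cbind(intercept = 1, t = rnorm(n), c1 = rnorm(n))
    g <- rnorm(n)
    y <- 0.5 * base[, "t"] + 0.3 * g + rnorm(n, sd = 0.5)
    y[sample(n, 5)] <- NA
    fit <- fitNestedLrt(y, base, g)
    expect_equal(fit$lrtStat, lmLrt(y, base, g), tolerance = 1e-8)
  }
})

test_that("beta7 confidence intervals cover the simulated effect", {
  set.seed(3)
  hits <- 0
  for (i in 1:200) {
    n <- 368
    t <- rnorm(n); g <- sample(-2:2, n, TRUE, c(.05, .25, .4, .25, .05))
    y <- 0.5 * t + 0.3 * g + rnorm(n, sd = 0.5)
    base <- cbind(1, t)
    fit <- fitNestedLrt(y, base, g)
    ## standard error from the alternative-model fit
    X <- cbind(base, g)
    se <- sqrt(sum(stats::lm.fit(X, y)$residuals^2) / (n - 3) *
                 solve(crossprod(X))[3, 3])
    hits <- hits + (abs(fit$beta7 - 0.3) <= 1.96 * se)
  }
  expect_gte(hits / 200, 0.93)
})

test_that("constant and collinear added predictors are skipped with
           reasons", {
  n <- 30
  base <- cbind(1, rnorm(n))
  expect_identical(fitNestedLrt(rnorm(n), base, rep(2, n))$skip,
                   "added_predictor_constant")
  expect_identical(fitNestedLrt(rnorm(n), base, 3 * base[, 2])$skip,
                   "added_predictor_collinear")
})

test_that("Benjamini-Hochberg matches hand computations and the brute-force
           step-up", {
  expect_equal(benjaminiHochberg(0.04), 0.04)
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjaminiHochberg(c(0.001, 0.9)), c(0.002, 0.9))
  set.seed(4)
  for (m in c(10, 1000, 10000)) {
    p <- runif(m)^2
    expect_equal(benjaminiHochberg(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("screens recover injected edges, control the null, skip missing
           genes, and ignore pair order", {
  sim <- simulateCohort(cleanConfig(seed = 5, nSamples = 120))
  co <- residualize(sim$cohort)
  pairs <- interactionPairs(sim$truth, nDecoys = 300, seed = 5)
  res <- screenPairs(co, pairs, "cnv")
  ek <- paste(trueEdges(sim$truth)$controller, trueEdges(sim$truth)$controlled)
  hit <- paste(res$x, res$y)[res$fdr < 0.05]
  expect_gte(mean(ek %in% hit), 0.8)
  dk <- paste(pairs$x, pairs$y)[pairs$truth == "decoy"]
  expect_lte(mean(dk %in% hit), 0.05)
  ## unmeasured controller is skipped, not tested
  ghost <- rbind(pairs[1:3, ], data.frame(x = "not_a_gene", y = pairs$y[1],
                                          truth = "decoy"))
  res2 <- screenPairs(co, ghost, "cnv")
  expect_identical(attr(res2, "skipped")$reason, "gene_not_measured")
  ## order invariance
  shuf <- pairs[rev(seq_len(nrow(pairs))), ]
  res3 <- screenPairs(co, shuf, "cnv")
  m <- merge(res, res3, by = c("x", "y"))
  expect_equal(m$p.x, m$p.y, tolerance = 1e-12)
  expect_equal(m$fdr.x, m$fdr.y, tolerance = 1e-12)
})

test_that("null p-values are uniform under permutation of the added
           predictor", {
  set.seed(6)
  n <- 100
  base <- cbind(1, rnorm(n))
  y <- base[, 2] * 0.5 + rnorm(n)
  g <- sample(-2:2, n, TRUE, c(.05, .25, .4, .25, .05))
  p <- replicate(2000, fitNestedLrt(y, base, sample(g))$p)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("variant intersection uses strict FDR thresholds", {
  a <- data.frame(x = c("a", "b", "c"), y = c("y1", "y2", "y3"),
                  p = c(0.001, 0.002, 0.003), fdr = c(0.01, 0.05, 0.002))
  b <- data.frame(x = c("a", "b", "c"), y = c("y1", "y2", "y3"),
                  p = c(0.001, 0.001, 0.5), fdr = c(0.02, 0.01, 0.9))
  out <- intersectVariants(a, b)
  ## b fails CNV at exactly 0.05; c fails the mRNA screen
  expect_identical(out$x, "a")
  expect_identical(names(out)[ncol(out)], "mrnaFdr")
})

test_that("colocalization deduplication follows the Borda rule and the CNV
           correlation exception", {
  gm <- data.frame(gene = c("a", "b", "c"), chromosome = c(1, 1, 2))
  cnvHi <- matrix(c(rep(c(1, 0, -1, 2, 0), 4),
                    rep(c(1, 0, -1, 2, 0), 4),
                    rnorm(20)), 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  ## a and b share a chromosome and a CNV profile (r = 1): Borda keeps a
  ## (ranks 1+2 vs 2+1, tie broken by smaller CNV p)
  prs <- data.frame(x = c("a", "b"), y = "Y", p = c(0.001, 0.002),
                    mrnaP = c(0.004, 0.003))
  out <- deduplicateColocalized(prs, gm, cnvHi)
  expect_identical(out$x, "a")
  ## low CNV correlation keeps both
  cnvLo <- cnvHi
  set.seed(7)
  cnvLo["b", ] <- sample(-2:2, 20, TRUE)
  stopifnot(abs(cor(cnvLo["a", ], cnvLo["b", ])) < 0.5)
  out2 <- deduplicateColocalized(prs, gm, cnvLo)
  expect_identical(sort(out2$x), c("a", "b"))
  ## distinct chromosomes are unaffected
  prs3 <- data.frame(x = c("a", "c"), y = "Y", p = c(0.01, 0.02),
                     mrnaP = c(0.01, 0.02))
  expect_identical(nrow(deduplicateColocalized(prs3, gm, cnvHi)), 2L)
  ## a controlled gene always keeps at least one controller
  expect_gte(length(unique(out$y)), length(unique(prs$y)))
})

test_that("control status classification equals brute-force set algebra", {
  simple <- classifyControlStatus(data.frame(x = "A", y = "B"))
  expect_identical(simple$status[simple$gene == "A"], "controlling")
  expect_identical(simple$status[simple$gene == "B"], "controlled")
  chain <- classifyControlStatus(data.frame(x = c("A", "B"),
                                            y = c("B", "C")))
  expect_identical(chain$status[chain$gene == "B"], "both")
  set.seed(8)
  prs <- data.frame(x = sample(LETTERS[1:8], 30, TRUE),
                    y = sample(LETTERS[1:8], 30, TRUE))
  prs <- prs[prs$x != prs$y, ]
  got <- classifyControlStatus(prs)
  for (i in seq_len(nrow(got))) {
    g <- got$gene[i]
    want <- if (g %in% prs$x && g %in% prs$y) "both" else
      if (g %in% prs$x) "controlling" else "controlled"
    expect_identical(got$status[i], want)
  }
  expect_error(classifyControlStatus(data.frame(x = character(),
                                                y = character())), "empty")
})

test_that("phospho screen recovers regulatory sites, skips collinear sites
           and enforces the protein-level overlap", {
  sim <- simulateCohort(cleanConfig(seed = 9, nSamples = 150,
                                    fracPhosphoRegulatory = 0.3))
  co <- residualize(sim$cohort)
  pairs <- interactionPairs(sim$truth, nDecoys = 100, seed = 9)
  ph <- screenPhospho(co, pairs)
  reg <- phosphoRegulators(sim$truth)
  hit <- paste(ph$results$site, ph$results$y)[ph$results$fdr < 0.05]
  expect_gte(mean(paste(reg$site, reg$controlled) %in% hit), 0.8)
  ## site exactly collinear with the parent protein is skipped
  co2 <- co
  s1 <- phosphoMap(co)$site[1]
  g1 <- phosphoMap(co)$gene[1]
  co2@phospho[s1, ] <- proteinMatrix(co)[g1, ]
  one <- data.frame(x = g1, y = setdiff(pairs$y, g1)[1])
  out <- screenPhospho(co2, one)
  sk <- attr(out$results, "skipped")
  expect_true("added_predictor_collinear" %in%
                sk$reason[sk$site == s1] ||
              !(s1 %in% out$results$site))
  ## overlap rule: significant phospho pair not protein-significant drops out
  empty <- data.frame(x = character(), y = character())
  none <- screenPhospho(co, pairs, proteinPairs = empty)
  expect_identical(nrow(none$final), 0L)
})
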