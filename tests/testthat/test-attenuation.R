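mkCohort <- function(cnv, mrna, protein) {
  n <- ncol(cnv)
  cov <- data.frame(cancer_type = factor(rep("A", n)),
                    batch = factor(rep("b", n)),
                    technology = factor(rep("t", n)),
                    age = rep(50, n), gender = factor(rep("f", n)),
                    row.names = colnames(cnv))
  omicsCohort(cnv = cnv, mrna = mrna, protein = protein, covariates = cov)
}

test_that("attenuation potential is the difference of the two dosage
           correlations and vanishes when protein equals mRNA", {
  set.seed(1)
  n <- 60
  smp <- sprintf("s%02d", 1:n)
  cnv <- matrix(sample(-2:2, 2 * n, TRUE), 2, dimnames = list(c("g1", "g2"),
                                                              smp))
  mrna <- cnv + matrix(rnorm(2 * n, sd = 0.3), 2)
  co <- mkCohort(cnv, mrna, protein = mrna)
  att <- computeAttenuation(co)
  expect_equal(att$potential, c(0, 0), tolerance = 1e-12)
  expect_equal(att$rCnvMrna, att$rCnvProtein)
  ## arithmetic of the statistic itself
  expect_equal(0.7 - 0.2, 0.5)
  rec <- att[1, ]
  expect_equal(rec$potential, rec$rCnvMrna - rec$rCnvProtein,
               tolerance = 1e-12)
})

test_that("swapping mRNA and protein matrices negates every potential", {
  sim <- simulateCohort(smallConfig(seed = 7))
  co <- sim$cohort
  fwd <- computeAttenuation(co)
  swapped <- omicsCohort(cnv = cnvMatrix(co), mrna = proteinMatrix(co),
                         protein = mrnaMatrix(co),
                         covariates = sampleCovariates(co))
  rev <- computeAttenuation(swapped)
  shared <- intersect(fwd$gene, rev$gene)
  expect_equal(fwd$potential[match(shared, fwd$gene)],
               -rev$potential[match(shared, rev$gene)], tolerance = 1e-12)
})

test_that("genes below the minimum pair count are excluded with a reason", {
  set.seed(2)
  n <- 50
  smp <- sprintf("s%02d", 1:n)
  cnv <- matrix(sample(-1:1, n, TRUE), 1, dimnames = list("g1", smp))
  mrna <- cnv + rnorm(n)
  prot <- mrna
  prot[1, 1:40] <- NA
  att <- computeAttenuation(mkCohort(cnv, mrna, prot), minPairs = 20)
  expect_identical(attr(att, "excluded")$reason, "too_few_pairs")
})

test_that("mixture classification recovers generating classes and is
           deterministic", {
  set.seed(10)
  n <- 8000
  comp <- sample(1:4, n, TRUE)
  mu <- c(-0.1, 0.02, 0.25, 0.55)
  pot <- setNames(rnorm(n, mu[comp], 0.05), sprintf("g%04d", 1:n))
  truth <- c("non_attenuated", "non_attenuated", "low_attenuated",
             "high_attenuated")[comp]
  cls <- classifyAttenuation(pot)
  expect_gte(mean(as.character(cls$classes) == truth), 0.95)
  expect_true(all(diff(sort(cls$componentMeans)) > 0))
  ## ordered class means: non < low < high
  cm <- tapply(pot, cls$classes, mean)
  expect_true(cm["non_attenuated"] < cm["low_attenuated"])
  expect_true(cm["low_attenuated"] < cm["high_attenuated"])
  cls2 <- classifyAttenuation(pot)
  expect_identical(cls$classes, cls2$classes)
  expect_error(classifyAttenuation(rep(0.3, 100)), "constant")
  expect_error(classifyAttenuation(pot[1:20]), "at least")
})

test_that("complex enrichment matches the closed-form and exhaustive
           hypergeometric and applies the Jaccard filter", {
  universe <- sprintf("g%03d", 1:100)
  attSet <- universe[1:10]
  cxs <- list(full = universe[1:6])
  enr <- enrichComplexes(attSet, cxs, universe, minSize = 5)
  expect_equal(enr$p, 210 / choose(100, 6), tolerance = 1e-12)
  expect_equal(enr$p, 1.76e-7, tolerance = 0.01)
  disjoint <- enrichComplexes(attSet, list(c = universe[50:60]), universe,
                              minSize = 5)
  expect_gt(disjoint$p, 0.5)
  ## exhaustive-enumeration oracle on small universes
  set.seed(3)
  for (i in 1:10) {
    nu <- sample(10:20, 1)
    u <- sprintf("u%02d", seq_len(nu))
    att <- sample(u, sample(2:6, 1))
    cx <- list(x = sample(u, sample(6:nu, 1)))
    got <- enrichComplexes(att, cx, u, minSize = 5)
    ov <- length(intersect(cx$x, att))
    expect_equal(got$p, bruteHyperUpper(ov, length(att), nu, length(cx$x)),
                 tolerance = 1e-12)
  }
  ## near-duplicate complexes: later (smaller) one is dropped
  a <- sprintf("g%03d", 1:20)
  dup <- list(big = a, near = a[1:19])
  out <- enrichComplexes(attSet, dup, universe)
  expect_identical(out$complex, "big")
  expect_error(enrichComplexes(attSet, cxs, character()), "universe")
})

test_that("ROC AUC equals the Mann-Whitney concordance count", {
  perfect <- rocPairPrediction(c(TRUE, TRUE, FALSE, FALSE), c(4, 3, 2, 1))
  expect_equal(perfect$auc, 1)
  set.seed(4)
  labs <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  sc <- c(0.9, 0.4, 0.6, 0.5, 0.1, 0.3)
  roc <- rocPairPrediction(labs, sc)
  conc <- 0
  for (i in which(labs)) for (j in which(!labs))
    conc <- conc + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  expect_equal(roc$auc, conc / (3 * 3), tolerance = 1e-12)
  big <- rocPairPrediction(sample(c(TRUE, FALSE), 4000, TRUE), rnorm(4000))
  expect_equal(big$auc, 0.5, tolerance = 0.05)
  expect_error(rocPairPrediction(c(TRUE, TRUE), c(1, 2)), "both")
})

test_that("group comparisons: exact enumeration on small groups, normal
           approximation close to exact at moderate size", {
  same <- compareGroups(c(1:6, 1:6), rep(c("a", "b"), each = 6))
  expect_equal(same$p, 1, tolerance = 0.05)
  sep <- compareGroups(c(1, 2, 3, 4, 5, 6),
                       c("a", "a", "a", "b", "b", "b"))
  expect_equal(sep$p, 0.1, tolerance = 1e-12)
  set.seed(5)
  a <- rnorm(15); b <- rnorm(15, 0.5)
  pExact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  got <- compareGroups(c(a, b), rep(c("a", "b"), each = 15))$p
  expect_lt(abs(got - pExact), 0.02)
  expect_error(compareGroups(c(1, 2), c("a", "b")), ">= 2")
})

test_that("synthetic cohorts recover the simulated attenuated fraction and
           classes", {
  accs <- fracs <- numeric(0)
  for (s in 1:5) {
    sim <- simulateCohort(simulationConfig(nGenes = 800, nComplexes = 80,
                                           seed = s))
    att <- computeAttenuation(residualize(sim$cohort))
    cls <- classifyAttenuation(setNames(att$potential, att$gene), seed = s)
    truth <- trueClasses(sim$truth)[att$gene]
    accs <- c(accs, mean(as.character(cls$classes) == truth))
    fracs <- c(fracs, mean(cls$classes != "non_attenuated"))
  }
  expect_gte(mean(accs), 0.9)
  expect_lt(abs(mean(fracs) - 0.42), 0.05)
})
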