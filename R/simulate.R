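#' Simulate a matched multi-omics cancer cohort with known ground truth
#'
#' Generates aligned CNV / mRNA / protein / phosphosite matrices under the
#' generative model the downstream analysis assumes: discretized GISTIC
#' copy-number levels propagate linearly to mRNA; for most genes protein
#' tracks its own mRNA, while for attenuated genes the protein level is a
#' mixture of its own mRNA and the realized protein abundance of a
#' controlling subunit drawn from the same protein complex (buffering
#' strength `b`); regulatory phosphosites on a controller add an extra
#' effect on the controlled protein. Covariate effects (cancer type, batch,
#' technology, age, gender) are additive on the log scale, genes within a
#' colocalization block share one CNV profile, and missingness is applied
#' completely at random.
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return A list with elements `cohort` ([OmicsCohort-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' sim <- simulateCohort(simulationConfig(nSamples = 50, nGenes = 300,
#'                                        nComplexes = 30, seed = 7))
#' sim$cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  nS <- config@nSamples; nG <- config@nGenes
  genes <- sprintf("g%04d", seq_len(nG))
  samples <- sprintf("s%03d", seq_len(nS))

  ## gene map: chromosomes, positions, colocalization blocks
  chrom <- sort(rep_len(seq_len(config@nChromosomes), nG))
  pos <- unlist(lapply(split(seq_len(nG), chrom), seq_along), use.names = FALSE)
  blockWithin <- (pos - 1L) %/% config@colocalizationBlockSize
  block <- as.integer(factor(paste(chrom, blockWithin)))
  map <- data.frame(gene = genes, chromosome = chrom, position = pos,
                    block = block, stringsAsFactors = FALSE)

  ## complexes: disjoint membership; first member is the controlling subunit
  sizeChoices <- seq(config@complexSizeRange[1], config@complexSizeRange[2])
  sizes <- sizeChoices[sample.int(length(sizeChoices), config@nComplexes,
                                  replace = TRUE)]
  if (sum(sizes) > nG)
    stop("complex membership demand (", sum(sizes),
         " genes) exceeds nGenes (", nG, ")")
  members <- sample(genes, sum(sizes))
  complexes <- split(members, rep(seq_along(sizes), sizes))
  names(complexes) <- sprintf("complex_%03d", seq_along(complexes))
  controllers <- vapply(complexes, `[`, character(1), 1L)

  ## attenuation classes
  nAtt <- round(config@fracAttenuated * nG)
  candidates <- setdiff(members, controllers)
  if (nAtt > length(candidates))
    stop("cannot place ", nAtt, " attenuated genes: only ",
         length(candidates), " non-controller complex members available; ",
         "increase nComplexes or complexSizeRange")
  attGenes <- sample(candidates, nAtt)
  highGenes <- sample(attGenes, round(config@fracHighAttenuated * nAtt))
  classes <- setNames(rep("non_attenuated", nG), genes)
  classes[attGenes] <- "low_attenuated"
  classes[highGenes] <- "high_attenuated"

  geneComplex <- setNames(rep(names(complexes), sizes), members)
  edges <- data.frame(
    controller = unname(controllers[geneComplex[attGenes]]),
    controlled = attGenes,
    buffering = ifelse(classes[attGenes] == "high_attenuated",
                       config@bufferingHigh, config@bufferingLow),
    class = unname(classes[attGenes]), stringsAsFactors = FALSE)

  ## CNV: one GISTIC draw per colocalization block, shared by block members
  nBlocks <- max(block)
  blockCnv <- matrix(sample(GISTIC_LEVELS, nBlocks * nS, replace = TRUE,
                            prob = config@cnvLevelProbs),
                     nrow = nBlocks)
  cnv <- blockCnv[block, , drop = FALSE]
  dimnames(cnv) <- list(genes, samples)

  ## sample covariates
  covariates <- data.frame(
    cancer_type = factor(sample(c("BRCA", "COREAD", "OV"), nS, TRUE)),
    batch = factor(sample(paste0("batch", 1:4), nS, TRUE)),
    technology = factor(sample(c("TMT", "labelfree"), nS, TRUE)),
    age = rnorm(nS, 60, 10),
    gender = factor(sample(c("female", "male"), nS, TRUE)),
    row.names = samples)

  D <- model.matrix(~ cancer_type + batch + technology + scale(age) + gender,
                    covariates)[, -1, drop = FALSE]
  covOf <- c(cancer_type = "cancer_type", batch = "batch",
             technology = "technology", `scale(age)` = "age",
             gender = "gender")
  colSd <- config@covariateEffectSds[
    covOf[vapply(colnames(D), function(cn)
      names(covOf)[startsWith(cn, names(covOf))][1], character(1))]]
  drawEffects <- function() {
    B <- matrix(rnorm(nG * ncol(D)), nG) %*% diag(colSd, ncol(D))
    B %*% t(D)
  }

  mrna <- config@mrnaDosageSlope * cnv + drawEffects() +
    matrix(rnorm(nG * nS, 0, config@noiseSdMrna), nG)
  dimnames(mrna) <- list(genes, samples)

  protein <- mrna + drawEffects() +
    matrix(rnorm(nG * nS, 0, config@noiseSdProtein), nG)
  ## buffering: controlled protein tracks the controller's realized protein
  for (i in seq_len(nrow(edges))) {
    g <- edges$controlled[i]; b <- edges$buffering[i]
    protein[g, ] <- (1 - b) * mrna[g, ] +
      b * protein[edges$controller[i], ] +
      rnorm(nS, 0, config@noiseSdProtein)
  }
  dimnames(protein) <- list(genes, samples)

  ## phosphosites: one site on most proteins, tracking the parent protein
  siteGenes <- sort(sample(genes, round(0.8 * nG)))
  positions <- sample(50:900, length(siteGenes), replace = TRUE)
  sites <- sprintf("%s_S%d", siteGenes, positions)
  phospho <- protein[siteGenes, , drop = FALSE] +
    matrix(rnorm(length(siteGenes) * nS, 0, config@noiseSdPhospho),
           length(siteGenes))
  rownames(phospho) <- sites

  ## regulatory phosphosites: site-specific signal u on the controller
  ## feeds forward into the controlled protein with effect phosphoBeta
  nReg <- round(config@fracPhosphoRegulatory * nrow(edges))
  regIdx <- if (nReg > 0) sample(seq_len(nrow(edges)), nReg) else integer()
  phosphoReg <- data.frame(site = character(), controller = character(),
                           controlled = character(), beta = numeric(),
                           stringsAsFactors = FALSE)
  for (i in regIdx) {
    ctrl <- edges$controller[i]
    ## u is the site's full deviation from the parent protein, so the
    ## nested-model coefficient of the measured site equals phosphoBeta
    u <- rnorm(nS, 0, 0.5)
    site <- sprintf("%s_S%d", ctrl, sample(50:900, 1))
    while (site %in% rownames(phospho))
      site <- sprintf("%s_S%d", ctrl, sample(50:900, 1))
    phospho <- rbind(phospho, matrix(
      protein[ctrl, ] + u, 1, dimnames = list(site, samples)))
    protein[edges$controlled[i], ] <- protein[edges$controlled[i], ] +
      config@phosphoBeta * u
    phosphoReg <- rbind(phosphoReg, data.frame(
      site = site, controller = ctrl, controlled = edges$controlled[i],
      beta = config@phosphoBeta, stringsAsFactors = FALSE))
  }
  phMap <- data.frame(site = rownames(phospho),
                      gene = sub("_S\\d+$", "", rownames(phospho)),
                      position = as.integer(sub(".*_S", "",
                                                rownames(phospho))),
                      stringsAsFactors = FALSE)

  ## colocalized passengers: block-mates of controllers, paired with the
  ## same controlled gene in the candidate list (spurious by construction)
  passengers <- data.frame(passenger = character(), controlled = character(),
                           controller = character(), stringsAsFactors = FALSE)
  nPass <- round(config@fracColocalized * nrow(edges))
  passIdx <- if (nPass > 0) sample(seq_len(nrow(edges)), nPass) else integer()
  for (i in passIdx) {
    ctrl <- edges$controller[i]
    mates <- setdiff(map$gene[map$block == map$block[map$gene == ctrl]],
                     c(ctrl, edges$controlled[i]))
    mates <- setdiff(mates, edges$controlled)
    if (length(mates))
      passengers <- rbind(passengers, data.frame(
        passenger = mates[1], controlled = edges$controlled[i],
        controller = ctrl, stringsAsFactors = FALSE))
  }

  ## missingness, completely at random
  protein[matrix(runif(length(protein)) < config@missingRateProtein,
                 nrow(protein))] <- NA
  phospho[matrix(runif(length(phospho)) < config@missingRatePhospho,
                 nrow(phospho))] <- NA

  cohort <- omicsCohort(cnv = cnv, mrna = mrna, protein = protein,
                        phospho = phospho, phosphoMap = phMap,
                        covariates = covariates)
  truth <- new("GroundTruth", classes = classes, edges = edges,
               complexes = complexes, geneMap = map,
               phosphoRegulators = phosphoReg, passengers = passengers)
  list(cohort = cohort, truth = truth)
}

#' Build a candidate physical-interaction pair list from ground truth
#'
#' Emulates a physical-interaction compendium: every true controlling edge,
#' the colocalized passenger pairs recorded in the ground truth, and random
#' decoy pairs with no generative relationship.
#'
#' @param truth a [GroundTruth-class].
#' @param nDecoys number of random decoy pairs.
#' @param seed RNG seed for decoy sampling.
#' @return data.frame with columns `x`, `y` (directed candidate pair) and
#'   `truth` (`edge`, `passenger` or `decoy`).
#' @export
interactionPairs <- function(truth, nDecoys = 2L * nrow(trueEdges(truth)),
                             seed = 1L) {
  set.seed(seed)
  edges <- trueEdges(truth)
  genes <- names(trueClasses(truth))
  out <- data.frame(x = edges$controller, y = edges$controlled,
                    truth = rep("edge", nrow(edges)),
                    stringsAsFactors = FALSE)
  if (nrow(truth@passengers))
    out <- rbind(out, data.frame(x = truth@passengers$passenger,
                                 y = truth@passengers$controlled,
                                 truth = "passenger",
                                 stringsAsFactors = FALSE))
  seen <- paste(out$x, out$y)
  n <- 0L
  while (n < nDecoys) {
    x <- sample(genes, nDecoys, replace = TRUE)
    y <- sample(genes, nDecoys, replace = TRUE)
    ok <- x != y & !(paste(x, y) %in% seen)
    add <- head(which(ok), nDecoys - n)
    if (length(add)) {
      out <- rbind(out, data.frame(x = x[add], y = y[add], truth = "decoy",
                                   stringsAsFactors = FALSE))
      seen <- c(seen, paste(x[add], y[add]))
      n <- n + length(add)
    }
  }
  out
}

#' Simulate a normal-tissue expression panel
#'
#' Genes get independent mRNA profiles across tissues; protein tracks the
#' gene's own mRNA except for controlled genes, whose protein profile mixes
#' in the controlling subunit's mRNA at the edge's buffering strength.
#'
#' @param truth a [GroundTruth-class].
#' @param nTissues number of tissues (14 in the reference panels).
#' @param noiseSd protein residual s.d.
#' @param missingRate per-entry missingness rate in both matrices.
#' @param bOverride optional single buffering strength overriding the
#'   per-edge ground-truth values (0 switches buffering off).
#' @param seed RNG seed.
#' @return list with gene x tissue matrices `mrna` and `protein`.
#' @export
simulateTissuePanel <- function(truth, nTissues = 14L, noiseSd = 0.3,
                                missingRate = 0, bOverride = NULL,
                                seed = 1L) {
  set.seed(seed)
  genes <- names(trueClasses(truth))
  tissues <- sprintf("tissue%02d", seq_len(nTissues))
  nG <- length(genes)
  mrna <- matrix(rnorm(nG * nTissues), nG, dimnames = list(genes, tissues))
  protein <- mrna + matrix(rnorm(nG * nTissues, 0, noiseSd), nG)
  edges <- trueEdges(truth)
  for (i in seq_len(nrow(edges))) {
    b <- if (is.null(bOverride)) edges$buffering[i] else bOverride
    g <- edges$controlled[i]
    protein[g, ] <- (1 - b) * mrna[g, ] + b * mrna[edges$controller[i], ] +
      rnorm(nTissues, 0, noiseSd)
  }
  dimnames(protein) <- list(genes, tissues)
  if (missingRate > 0) {
    mrna[matrix(runif(nG * nTissues) < missingRate, nG)] <- NA
    protein[matrix(runif(nG * nTissues) < missingRate, nG)] <- NA
  }
  list(mrna = mrna, protein = protein)
}

#' Simulate cis-eQTL, LD and GWAS-catalogue tables
#'
#' Each gene's eQTLs fall into latent LD blocks (within-block r-squared above
#' the tagging threshold); tissue slope signs are consistent per block; the
#' probability that a block tags a GWAS variant is multiplied by a
#' class-specific factor, lowering the tagging fraction for attenuated genes.
#'
#' @param truth a [GroundTruth-class].
#' @param meanBlocksPerGene Poisson mean of LD blocks per gene (plus one).
#' @param variantsPerBlock eQTL variants per block.
#' @param nTissuesRange (min, max) tissues a variant is called in.
#' @param baseTagging GWAS-tagging probability for non-attenuated genes.
#' @param taggingFactorLow,taggingFactorHigh multiplicative factors for the
#'   low and high attenuation classes.
#' @param r2Within within-block LD r-squared.
#' @param seed RNG seed.
#' @return list of data.frames: `eqtl` (variant, gene, tissue, slope), `ld`
#'   (variantA, variantB, r2), `gwas` (character vector of variants), and
#'   `blockTruth` (gene, block, tagged).
#' @export
simulateEqtlTables <- function(truth, meanBlocksPerGene = 4,
                               variantsPerBlock = 3L,
                               nTissuesRange = c(3L, 10L),
                               baseTagging = 0.4, taggingFactorLow = 0.75,
                               taggingFactorHigh = 0.5, r2Within = 0.9,
                               seed = 1L) {
  set.seed(seed)
  classes <- trueClasses(truth)
  genes <- names(classes)
  factorOf <- c(non_attenuated = 1, low_attenuated = taggingFactorLow,
                high_attenuated = taggingFactorHigh)
  eqtl <- list(); ld <- list(); gwas <- character(); bt <- list()
  vid <- 0L
  for (g in genes) {
    nb <- rpois(1, meanBlocksPerGene) + 1L
    pTag <- baseTagging * factorOf[[classes[[g]]]]
    for (b in seq_len(nb)) {
      vs <- sprintf("rs%06d", vid + seq_len(variantsPerBlock))
      vid <- vid + variantsPerBlock
      if (variantsPerBlock > 1L) {
        cmb <- utils::combn(vs, 2)
        ld[[length(ld) + 1L]] <- data.frame(
          variantA = cmb[1, ], variantB = cmb[2, ], r2 = r2Within,
          stringsAsFactors = FALSE)
      }
      nt <- sample(seq(nTissuesRange[1], nTissuesRange[2]), 1)
      sgn <- sample(c(-1, 1), 1)
      for (v in vs)
        eqtl[[length(eqtl) + 1L]] <- data.frame(
          variant = v, gene = g, tissue = sprintf("t%02d", seq_len(nt)),
          slope = sgn * runif(nt, 0.1, 1), stringsAsFactors = FALSE)
      tagged <- runif(1) < pTag
      if (tagged) {
        if (runif(1) < 0.5) {
          gwas <- c(gwas, vs[1])
        } else {        # tag through an LD proxy outside the eQTL set
          proxy <- sprintf("rsP%06d", vid)
          ld[[length(ld) + 1L]] <- data.frame(
            variantA = vs[1], variantB = proxy, r2 = r2Within,
            stringsAsFactors = FALSE)
          gwas <- c(gwas, proxy)
        }
      }
      bt[[length(bt) + 1L]] <- data.frame(gene = g, block = b,
                                          tagged = tagged)
    }
  }
  list(eqtl = do.call(rbind, eqtl), ld = do.call(rbind, ld),
       gwas = unique(gwas), blockTruth = do.call(rbind, bt))
}

#' Write a toy multi-chain structure in PDB format
#'
#' Builds pseudo-atom chains (one C-alpha carbon per residue, laid out along
#' a straight line) at controlled coordinates, so that interface residues
#' are known by construction, and writes a syntactically valid PDB file.
#'
#' @param chains list of chain specs; each a list with `chain` (single
#'   letter), `n` (residue count), `origin` (xyz, Angstrom), and optionally
#'   `direction` (unit-ish vector, default x axis) and `spacing`
#'   (inter-residue distance, default 3.8 Angstrom).
#' @param file output path.
#' @return The file path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' makeToyComplex(list(list(chain = "A", n = 8, origin = c(0, 0, 0)),
#'                     list(chain = "B", n = 8, origin = c(0, 4, 0))), f)
#' @export
makeToyComplex <- function(chains, file) {
  if (!is.list(chains) || !length(chains))
    stop("'chains' must be a nonempty list of chain specs")
  xyz <- NULL; ch <- character(); resno <- integer()
  for (cs in chains) {
    if (is.null(cs$chain) || is.null(cs$n) || is.null(cs$origin) ||
        cs$n < 1 || length(cs$origin) != 3)
      stop("malformed chain spec: need 'chain', 'n' >= 1, 'origin' (xyz)")
    dir <- if (is.null(cs$direction)) c(1, 0, 0) else cs$direction
    dir <- dir / sqrt(sum(dir^2))
    spacing <- if (is.null(cs$spacing)) 3.8 else cs$spacing
    pts <- t(vapply(seq_len(cs$n) - 1L,
                    function(i) cs$origin + i * spacing * dir, numeric(3)))
    xyz <- rbind(xyz, pts)
    ch <- c(ch, rep(cs$chain, cs$n))
    resno <- c(resno, seq_len(cs$n))
  }
  n <- nrow(xyz)
  bio3d::write.pdb(file = file, xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", n), resno = resno,
                   resid = rep("ALA", n), eleno = seq_len(n),
                   elety = rep("CA", n), chain = ch,
                   o = rep(1, n), b = rep(0, n), elesy = rep("C", n))
  invisible(file)
}
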