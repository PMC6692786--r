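## Van der Waals radii by element (Bondi-type set) and theoretical maximum
## accessible surface areas per residue (Tien et al. tripeptide values),
## used to turn absolute SASA into relative SASA.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

## Quasi-uniform points on the unit sphere (golden spiral; deterministic).
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Read a PDB structure into an atom table
#'
#' Parses ATOM records with bio3d, strips hetero atoms, waters and
#' hydrogens, and attaches van der Waals radii by element.
#'
#' @param file path to a PDB file.
#' @param chainProteins optional named character vector mapping chain id to
#'   protein id (stored for downstream interface bookkeeping).
#' @return list of class `StructureModel`: `id`, `atoms` (data.frame with
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`, `radius`) and
#'   `proteins`.
#' @export
readStructure <- function(file, chainProteins = NULL) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  elem <- toupper(trimws(elem))
  a <- a[elem != "H", , drop = FALSE]
  elem <- elem[elem != "H"]
  radius <- unname(VDW_RADII[elem])
  radius[is.na(radius)] <- VDW_RADII[["C"]]
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      elety = a$elety, x = a$x, y = a$y, z = a$z,
                      radius = radius, stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", file)
  structure(list(id = sub("\\.pdb$", "", basename(file)), atoms = atoms,
                 proteins = chainProteins), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$id, "-", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' For each atom, a quasi-uniform point sphere is placed at radius
#' (van der Waals + probe); a point is accessible when it lies outside
#' every other inflated atom sphere, and the atom SASA is the accessible
#' fraction of `4 * pi * (r + probe)^2`. Residue SASA sums the atoms;
#' relative SASA divides by the residue type's tabulated maximum (absolute
#' only, with a warning, for unknown residue types).
#'
#' @param model a `StructureModel` from [readStructure()], or its `atoms`
#'   data.frame.
#' @param probeRadius solvent probe radius in Angstrom (water: 1.4).
#' @param nSpherePoints test points per atom sphere.
#' @return data.frame per residue: `chain`, `resno`, `resid`, `sasa`
#'   (square Angstrom), `relSasa`; per-atom areas in `attr(, "atomSasa")`.
#' @export
computeSasa <- function(model, probeRadius = 1.4, nSpherePoints = 960L) {
  atoms <- if (inherits(model, "StructureModel")) model$atoms else model
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atoms$radius + probeRadius
  pts <- spherePoints(nSpherePoints)
  atomArea <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(nb)) {
      acc <- nSpherePoints
    } else {
      p <- pts * R[i]
      px <- p[, 1] + xyz[i, 1]; py <- p[, 2] + xyz[i, 2]
      pz <- p[, 3] + xyz[i, 3]
      buried <- rep(FALSE, nSpherePoints)
      for (j in nb[order(d2[nb])]) {
        free <- which(!buried)
        if (!length(free)) break
        dd <- (px[free] - xyz[j, 1])^2 + (py[free] - xyz[j, 2])^2 +
          (pz[free] - xyz[j, 3])^2
        buried[free[dd < R[j]^2]] <- TRUE
      }
      acc <- sum(!buried)
    }
    atomArea[i] <- acc / nSpherePoints * 4 * pi * R[i]^2
  }
  key <- paste(atoms$chain, atoms$resno)
  first <- !duplicated(key)
  res <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    resid = atoms$resid[first],
                    sasa = as.numeric(tapply(atomArea, factor(key, levels =
                                               key[first]), sum)),
                    stringsAsFactors = FALSE)
  res$relSasa <- res$sasa / MAX_ASA[res$resid]
  if (anyNA(res$relSasa))
    warning("unknown residue type(s): ",
            paste(unique(res$resid[is.na(res$relSasa)]), collapse = ", "),
            "; absolute SASA only")
  attr(res, "atomSasa") <- atomArea
  res
}

#' Extract interface residues of a binary (or larger) complex
#'
#' Computes per-residue relative SASA in the full complex and in each chain
#' isolated; a residue belongs to the interface when its relative solvent
#' accessibility changes by more than `tolerance` between the unbound and
#' bound states. Also reports each chain's buried surface fraction,
#' (SASA unbound - SASA bound) / SASA unbound.
#'
#' @param model a `StructureModel` with at least two chains.
#' @param probeRadius,nSpherePoints passed to [computeSasa()].
#' @param tolerance minimum relative-SASA change defining an interface
#'   residue (absolute SASA change of `tolerance * 100` square Angstrom for
#'   residue types without a tabulated maximum).
#' @return list of class `InterfaceSummary`: `structure`, `proteins`,
#'   `interface` (per-chain residue numbers), `interfaceSizePerChain`,
#'   `interfaceSizeTotal`, `buriedFraction` (per chain), and `residues`
#'   (per-residue bound/unbound accessibilities).
#' @export
extractInterface <- function(model, probeRadius = 1.4,
                             nSpherePoints = 960L, tolerance = 1e-4) {
  atoms <- model$atoms
  chains <- unique(atoms$chain)
  if (length(chains) < 2) stop("interface extraction needs >= 2 chains")
  bound <- computeSasa(atoms, probeRadius, nSpherePoints)
  resRows <- list(); interface <- list(); buried <- numeric()
  for (ch in chains) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    unb <- suppressWarnings(computeSasa(sub, probeRadius, nSpherePoints))
    bsub <- bound[bound$chain == ch, , drop = FALSE]
    stopifnot(identical(unb$resno, bsub$resno))
    dRel <- abs(unb$relSasa - bsub$relSasa)
    dAbs <- abs(unb$sasa - bsub$sasa)
    isIf <- ifelse(is.na(dRel), dAbs > tolerance * 100, dRel > tolerance)
    interface[[ch]] <- unb$resno[isIf]
    totalUnb <- sum(unb$sasa)
    if (totalUnb <= 0) stop("zero unbound SASA for chain ", ch)
    buried[ch] <- (totalUnb - sum(bsub$sasa)) / totalUnb
    resRows[[ch]] <- data.frame(chain = ch, resno = unb$resno,
                                resid = unb$resid, sasaUnbound = unb$sasa,
                                sasaBound = bsub$sasa,
                                relUnbound = unb$relSasa,
                                relBound = bsub$relSasa,
                                isInterface = isIf,
                                stringsAsFactors = FALSE)
  }
  structure(list(
    structure = model$id, proteins = model$proteins, interface = interface,
    interfaceSizePerChain = vapply(interface, length, 1L),
    interfaceSizeTotal = sum(vapply(interface, length, 1L)),
    buriedFraction = buried,
    residues = do.call(rbind, resRows)), class = "InterfaceSummary")
}

#' @export
print.InterfaceSummary <- function(x, ...) {
  cat("InterfaceSummary", x$structure, "-", x$interfaceSizeTotal,
      "interface residues (",
      paste(names(x$interface), x$interfaceSizePerChain, sep = ":",
            collapse = ", "), ")\n")
  invisible(x)
}

#' Quality-filter binary complex structures
#'
#' Drops protein homodimers, structures with fewer than 100 modelled
#' residues in total, structures with any chain longer than its UniProt
#' protein length, structures whose two chains have equal length, and
#' structures with an unresolvable protein id.
#'
#' @param structures list; each element needs `id`, `proteins` (named by
#'   chain) and `chainLengths` (named by chain).
#' @param uniprotLengths named integer vector of protein lengths.
#' @return The retained structures; dropped ids and reasons in
#'   `attr(, "dropped")`.
#' @export
filterStructures <- function(structures, uniprotLengths) {
  dropped <- list()
  keep <- vapply(structures, function(s) {
    reason <- NULL
    if (!all(s$proteins %in% names(uniprotLengths)))
      reason <- "unknown_protein"
    else if (anyDuplicated(unname(s$proteins)))
      reason <- "homodimer"
    else if (sum(s$chainLengths) < 100)
      reason <- "fewer_than_100_residues"
    else if (any(s$chainLengths > uniprotLengths[s$proteins[
      names(s$chainLengths)]]))
      reason <- "chain_longer_than_uniprot"
    else if (length(s$chainLengths) == 2 &&
             s$chainLengths[1] == s$chainLengths[2])
      reason <- "equal_chain_lengths"
    if (!is.null(reason)) {
      dropped[[length(dropped) + 1L]] <<- data.frame(id = s$id,
                                                     reason = reason)
      return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- structures[keep]
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(id = character(), reason = character())
  out
}

#' Fraction of a protein's residues at interfaces
#'
#' Union of the protein's interface residue numbers across all retained
#' structures, divided by the UniProt protein length; capped at 1 with a
#' warning if the modelled union exceeds the sequence length.
#'
#' @param protein protein id.
#' @param summaries list of `InterfaceSummary` objects (with `proteins`
#'   chain maps).
#' @param proteinLength UniProt length of the protein.
#' @return Proportion in `[0, 1]`.
#' @export
interfaceFraction <- function(protein, summaries, proteinLength) {
  stopifnot(proteinLength > 0)
  resUnion <- integer()
  for (s in summaries) {
    if (is.null(s$proteins)) next
    for (ch in names(s$proteins)[s$proteins == protein])
      resUnion <- union(resUnion, s$interface[[ch]])
  }
  frac <- length(resUnion) / proteinLength
  if (frac > 1) {
    warning("interface residue union exceeds protein length for ", protein,
            "; capped at 1")
    frac <- 1
  }
  frac
}

#' Buried surface fraction of a chain within its complex
#'
#' @param summary an `InterfaceSummary`.
#' @param chain chain id.
#' @return (SASA unbound - SASA bound) / SASA unbound for that chain.
#' @export
buriedFraction <- function(summary, chain) {
  if (!chain %in% names(summary$buriedFraction))
    stop("chain ", chain, " not in summary")
  unname(summary$buriedFraction[chain])
}

#' Correlate association statistics with interface size
#'
#' Pearson correlation (with two-sided t-test p-values) of the interface
#' size with the CNV effect size and with -log10 FDR of the matching
#' protein associations.
#'
#' @param associations data.frame with `beta7` and `fdr` columns.
#' @param interfaceSize numeric vector, one size per association.
#' @return data.frame: `measure`, `r`, `p`, `n`.
#' @export
correlateInterfaceWithStats <- function(associations, interfaceSize) {
  stopifnot(nrow(associations) == length(interfaceSize))
  ok <- !is.na(interfaceSize) & !is.na(associations$beta7) &
    !is.na(associations$fdr)
  if (sum(ok) < 3) stop("need >= 3 paired observations")
  sz <- interfaceSize[ok]
  if (sd(sz) == 0) stop("interface sizes are constant")
  ct1 <- stats::cor.test(associations$beta7[ok], sz)
  ct2 <- stats::cor.test(-log10(associations$fdr[ok]), sz)
  data.frame(measure = c("beta7", "neglog10_fdr"),
             r = c(ct1$estimate, ct2$estimate),
             p = c(ct1$p.value, ct2$p.value), n = sum(ok),
             row.names = NULL, stringsAsFactors = FALSE)
}
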