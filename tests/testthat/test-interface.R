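test_that("SASA of an isolated atom matches the analytic sphere and
           converges with sphere-point density", {
  a <- toyAtoms(matrix(0, 1, 3))
  s <- suppressWarnings(computeSasa(a))
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(s$sasa, analytic, tolerance = 0.005)
  ## convergence: doubling the point count moves any residue < 0.5%
  f <- tempfile(fileext = ".pdb")
  makeToyComplex(list(list(chain = "A", n = 8, origin = c(0, 0, 0)),
                      list(chain = "B", n = 4, origin = c(4, 4.2, 0))), f)
  m <- readStructure(f)
  s1 <- suppressWarnings(computeSasa(m, nSpherePoints = 960L))
  s2 <- suppressWarnings(computeSasa(m, nSpherePoints = 1920L))
  expect_lt(max(abs(s1$sasa - s2$sasa) / s2$sasa), 0.005)
})

test_that("two-sphere burial matches the analytic spherical-cap formula", {
  two <- toyAtoms(rbind(c(0, 0, 0), c(3, 0, 0)))
  s <- suppressWarnings(computeSasa(two))
  R <- 1.7 + 1.4
  h <- R - 3 / 2                      # cap height for equal spheres
  expected <- 4 * pi * R^2 - 2 * pi * R * h
  atomAreas <- attr(s, "atomSasa")
  expect_equal(atomAreas[1], expected, tolerance = 0.01 * expected)
  expect_equal(atomAreas[2], expected, tolerance = 0.01 * expected)
})

test_that("occlusion is monotone and interfaces are symmetric, rigid-body
           invariant and equal to the distance oracle on convex toys", {
  f <- tempfile(fileext = ".pdb")
  makeToyComplex(list(list(chain = "A", n = 8, origin = c(0, 0, 0)),
                      list(chain = "B", n = 4, origin = c(4, 4.2, 0))), f)
  m <- readStructure(f)
  isum <- suppressWarnings(extractInterface(m))
  ## monotone occlusion, exact at fixed sphere points
  expect_true(all(isum$residues$sasaBound <= isum$residues$sasaUnbound +
                    1e-9))
  ## symmetry: both chains have interface residues or neither does
  sizes <- isum$interfaceSizePerChain
  expect_true(all(sizes > 0) || all(sizes == 0))
  ## distance-threshold oracle (2 * probe + r_i + r_j)
  at <- m$atoms
  for (ch in c("A", "B")) {
    mine <- at[at$chain == ch, ]; other <- at[at$chain != ch, ]
    hit <- vapply(seq_len(nrow(mine)), function(i)
      any(sqrt((mine$x[i] - other$x)^2 + (mine$y[i] - other$y)^2 +
                 (mine$z[i] - other$z)^2) <
            2 * 1.4 + mine$radius[i] + other$radius), logical(1))
    expect_identical(sort(isum$interface[[ch]]), sort(mine$resno[hit]))
  }
  ## rigid-body transformation: rotate + translate the whole complex
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% Rz + 10
  m2 <- m
  m2$atoms[, c("x", "y", "z")] <- xyz
  isum2 <- suppressWarnings(extractInterface(m2))
  expect_identical(isum$interface, isum2$interface)
  ## the scalar burial carries point-sampling quadrature noise under
  ## rotation; the interface sets above are exactly invariant
  expect_equal(isum$buriedFraction, isum2$buriedFraction, tolerance = 0.02)
})

test_that("buried fraction matches its definition and limits", {
  f <- tempfile(fileext = ".pdb")
  makeToyComplex(list(list(chain = "A", n = 6, origin = c(0, 0, 0)),
                      list(chain = "B", n = 3, origin = c(2, 3.9, 0))), f)
  m <- readStructure(f)
  isum <- suppressWarnings(extractInterface(m))
  at <- m$atoms
  for (ch in c("A", "B")) {
    unb <- suppressWarnings(computeSasa(at[at$chain == ch, ]))
    bnd <- suppressWarnings(computeSasa(at))
    bnd <- bnd[bnd$chain == ch, ]
    expect_equal(buriedFraction(isum, ch),
                 (sum(unb$sasa) - sum(bnd$sasa)) / sum(unb$sasa),
                 tolerance = 1e-10)
  }
  ## far-apart partner: buried fraction 0
  f2 <- tempfile(fileext = ".pdb")
  makeToyComplex(list(list(chain = "A", n = 4, origin = c(0, 0, 0)),
                      list(chain = "B", n = 4, origin = c(0, 100, 0))), f2)
  i2 <- suppressWarnings(extractInterface(readStructure(f2)))
  expect_equal(unname(i2$buriedFraction), c(0, 0), tolerance = 1e-12)
  ## a single atom caged by a surrounding chain is almost fully buried
  cage <- expand.grid(x = c(-2.2, 0, 2.2), y = c(-2.2, 0, 2.2),
                      z = c(-2.2, 0, 2.2))
  cage <- cage[!(cage$x == 0 & cage$y == 0 & cage$z == 0), ]
  atoms <- rbind(toyAtoms(matrix(0, 1, 3), chain = "B", resno = 1),
                 toyAtoms(as.matrix(cage), chain = "A",
                          resno = seq_len(nrow(cage))))
  bnd <- suppressWarnings(computeSasa(atoms))
  unb <- suppressWarnings(computeSasa(atoms[atoms$chain == "B", ]))
  frac <- (unb$sasa - bnd$sasa[bnd$chain == "B"]) / unb$sasa
  expect_gt(frac, 0.9)
})

test_that("structure QC drops homodimers, short models, over-length and
           equal-length chains", {
  lens <- c(P1 = 300, P2 = 250, P3 = 400)
  mk <- function(id, prot, cl) list(id = id, proteins = prot,
                                    chainLengths = cl)
  structures <- list(
    mk("homo", c(A = "P1", B = "P1"), c(A = 120, B = 130)),
    mk("short", c(A = "P1", B = "P2"), c(A = 50, B = 49)),
    mk("atBoundary", c(A = "P1", B = "P2"), c(A = 50, B = 50 + 1)),
    mk("tooLong", c(A = "P1", B = "P2"), c(A = 350, B = 100)),
    mk("equalLen", c(A = "P1", B = "P2"), c(A = 150, B = 150)),
    mk("unknown", c(A = "P9", B = "P2"), c(A = 150, B = 140)),
    mk("good", c(A = "P1", B = "P3"), c(A = 200, B = 180)))
  out <- filterStructures(structures, lens)
  expect_identical(vapply(out, `[[`, "", "id"), c("atBoundary", "good"))
  dropped <- attr(out, "dropped")
  expect_identical(dropped$reason[dropped$id == "homo"], "homodimer")
  expect_identical(dropped$reason[dropped$id == "short"],
                   "fewer_than_100_residues")
  expect_identical(dropped$reason[dropped$id == "equalLen"],
                   "equal_chain_lengths")
})

test_that("interface fraction is the union over structures divided by the
           protein length", {
  mkSum <- function(id, res) structure(list(
    structure = id, proteins = c(A = "P1", B = "P2"),
    interface = list(A = res, B = integer()),
    buriedFraction = c(A = 0.1, B = 0.1)), class = "InterfaceSummary")
  s1 <- mkSum("s1", 1:10); s2 <- mkSum("s2", 6:15)
  expect_equal(interfaceFraction("P1", list(s1, s2), 100), 0.15)
  expect_equal(interfaceFraction("P1", list(), 100), 0)
  expect_warning(capped <- interfaceFraction("P1", list(mkSum("s3", 1:50)),
                                             30), "capped")
  expect_equal(capped, 1)
})

test_that("interface-size correlations match the textbook formula", {
  set.seed(1)
  beta <- runif(10, 0.1, 0.9)
  assoc <- data.frame(beta7 = beta, fdr = 10^-runif(10, 1, 6))
  prop <- correlateInterfaceWithStats(assoc, 50 * assoc$beta7)
  expect_equal(prop$r[prop$measure == "beta7"], 1, tolerance = 1e-12)
  sz <- rnorm(10, 40, 10)
  got <- correlateInterfaceWithStats(assoc, sz)
  manual <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(got$r[1], manual(assoc$beta7, sz), tolerance = 1e-12)
  expect_equal(got$r[2], manual(-log10(assoc$fdr), sz), tolerance = 1e-12)
  expect_error(correlateInterfaceWithStats(assoc[1:2, ], sz[1:2]), ">= 3")
})
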