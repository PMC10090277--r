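oneAtomMol <- function(id = "m", x = 0, y = 0, z = 0, charge = 1,
                       steric = 1) {
  molecule3D(id, data.frame(element = "X", x = x, y = y, z = z,
                            charge = charge, steric = steric,
                            hydrophobic = 0.5, donor = FALSE,
                            acceptor = TRUE))
}

test_that("Kabsch alignment removes translations and rotations exactly", {
  g <- genAlignedMolecules(syntheticSpec(seed = 2, n = 6))
  tpl <- g$molecules[[1]]
  # identity
  al0 <- kabschAlign(tpl, tpl)
  expect_equal(al0$rmsd, 0, tolerance = 1e-10)
  expect_equal(al0$rotation, diag(3), tolerance = 1e-10)
  # pure translation
  shifted <- tpl
  shifted@atoms$x <- shifted@atoms$x + 5
  al1 <- kabschAlign(tpl, shifted)
  expect_equal(al1$rmsd, 0, tolerance = 1e-10)
  expect_equal(coords(al1$molecule), coords(tpl), tolerance = 1e-10)
  # 90-degree rotation about z: recovered rotation equals its inverse
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rot <- tpl
  xyz <- coords(tpl) %*% t(R)
  rot@atoms$x <- xyz[, 1]; rot@atoms$y <- xyz[, 2]; rot@atoms$z <- xyz[, 3]
  al2 <- kabschAlign(tpl, rot)
  expect_equal(al2$rmsd, 0, tolerance = 1e-10)
  expect_equal(al2$rotation %*% R, diag(3), tolerance = 1e-9)
  expect_equal(det(al2$rotation), 1, tolerance = 1e-10)
})

test_that("alignment rejects underdetermined pairings", {
  tpl <- oneAtomMol()
  expect_error(kabschAlign(tpl, tpl, atomPairs = cbind(1, 1)), "3")
  line <- molecule3D("l", data.frame(element = "X", x = 0:3, y = 0, z = 0,
                                     charge = 0, steric = 1, hydrophobic = 0,
                                     donor = FALSE, acceptor = FALSE))
  expect_error(kabschAlign(line, line), "collinear")
})

test_that("grid arithmetic matches the 2 A spacing / 4 A margin rules", {
  g1 <- buildGrid(oneAtomMol(), spacing = 2, margin = 4)
  expect_equal(g1@counts, rep(5L, 3))       # coords -4,-2,0,2,4 per axis
  expect_equal(prod(g1@counts), 125)
  expect_equal(g1@origin, c(-4, -4, -4))
  two <- list(oneAtomMol("a"), oneAtomMol("b", x = 2))
  g2 <- buildGrid(two, spacing = 2, margin = 4)
  expect_equal(g2@counts, c(6L, 5L, 5L))    # x-extent -4..6
  expect_equal(prod(g2@counts), 150)
  expect_error(buildGrid(oneAtomMol(), spacing = 0), "spacing")
})

test_that("field values equal the closed-form Gaussian sum", {
  mol <- oneAtomMol()
  grid <- buildGrid(mol)
  f <- comsiaField(mol, grid, "E", alpha = 0.3)
  pts <- gridPoints(grid)
  # probe at the atom: exp(0) = 1, negative sign convention
  expect_equal(f[which(rowSums(abs(pts)) == 0)], -1, tolerance = 1e-12)
  # full lattice against an independent closed-form oracle
  expect_equal(f, fieldOracle(pts, coords(mol), 1, 0.3), tolerance = 1e-12)
  # probe 1 A away from a unit-weight atom
  mol1 <- oneAtomMol(x = 1)  # lattice point (0,0,0) sits 1 A from the atom
  f1 <- comsiaField(mol1, grid, "E", alpha = 0.3)
  expect_equal(f1[which(rowSums(abs(pts)) == 0)], -exp(-0.3),
               tolerance = 1e-12)
  # linearity: two identical atoms double the field everywhere
  dbl <- molecule3D("d", data.frame(element = "X", x = c(0, 0), y = 0, z = 0,
                                    charge = 1, steric = 1, hydrophobic = 0,
                                    donor = FALSE, acceptor = FALSE))
  expect_equal(comsiaField(dbl, grid, "E"), 2 * f, tolerance = 1e-12)
})

test_that("fields are invariant under joint rigid motion of molecule and grid", {
  g <- genAlignedMolecules(syntheticSpec(seed = 6, n = 6))
  mol <- g$molecules[[3]]
  grid <- buildGrid(mol, spacing = 2, margin = 4)
  f <- comsiaField(mol, grid, "S", alpha = 0.3)
  # translation: shift molecule and grid origin together
  shift <- c(1.3, -2.2, 0.7)
  molT <- mol
  molT@atoms$x <- molT@atoms$x + shift[1]
  molT@atoms$y <- molT@atoms$y + shift[2]
  molT@atoms$z <- molT@atoms$z + shift[3]
  gridT <- new("GridSpec", origin = grid@origin + shift,
               spacing = grid@spacing, counts = grid@counts)
  expect_equal(comsiaField(molT, gridT, "S"), f, tolerance = 1e-9)
  # 90-degree rotation about z maps the lattice onto another lattice
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  molR <- mol
  xyz <- coords(mol) %*% t(Rz)
  molR@atoms$x <- xyz[, 1]; molR@atoms$y <- xyz[, 2]; molR@atoms$z <- xyz[, 3]
  pts <- gridPoints(grid)
  ptsR <- pts %*% t(Rz)
  lo <- apply(ptsR, 2, min)
  gridR <- new("GridSpec", origin = lo, spacing = grid@spacing,
               counts = grid@counts[c(2, 1, 3)])
  fR <- comsiaField(molR, gridR, "S")
  ptsOfR <- gridPoints(gridR)
  key <- function(m) apply(round(m, 6), 1, paste, collapse = "/")
  idx <- match(key(ptsR), key(ptsOfR))
  expect_false(anyNA(idx))
  expect_equal(fR[idx], f, tolerance = 1e-9)
})

test_that("halving the spacing reproduces values at shared lattice points", {
  g <- genAlignedMolecules(syntheticSpec(seed = 8, n = 6))
  mol <- g$molecules[[1]]
  grid <- buildGrid(mol, spacing = 2, margin = 4)
  fine <- new("GridSpec", origin = grid@origin, spacing = 1,
              counts = 2L * (grid@counts - 1L) + 1L)
  fc <- comsiaField(mol, grid, "H")
  ff <- comsiaField(mol, fine, "H")
  key <- function(m) apply(round(m, 6), 1, paste, collapse = "/")
  idx <- match(key(gridPoints(grid)), key(gridPoints(fine)))
  expect_false(anyNA(idx))
  expect_equal(ff[idx], fc, tolerance = 1e-12)
})

test_that("field stacking errors on missing properties and labels blocks", {
  mol <- oneAtomMol()
  mol@atoms$charge <- NA_real_
  grid <- buildGrid(mol)
  expect_error(comsiaField(mol, grid, "E"), "E")
  g <- genAlignedMolecules(syntheticSpec(seed = 3, n = 8))
  ff <- comsiaFieldMatrix(g$molecules)
  expect_equal(nrow(ff@values), 8L)
  expect_equal(length(unique(ff@fieldLabels)), 5L)
  expect_equal(ncol(ff@values), 5L * prod(ff@grid@counts))
})

test_that("molecule JSON interchange round-trips", {
  g <- genAlignedMolecules(syntheticSpec(seed = 12, n = 6))
  tmp <- withr::local_tempfile(fileext = ".json")
  writeMoleculeSet(g$molecules, tmp)
  back <- readMoleculeSet(tmp)
  expect_equal(length(back), 6L)
  expect_equal(coords(back[[4]]), coords(g$molecules[[4]]),
               tolerance = 1e-12)
  expect_equal(atoms(back[[4]])$charge, atoms(g$molecules[[4]])$charge,
               tolerance = 1e-12)
})

test_that("SDF molecules get rule-based properties and tag overrides", {
  skip_if_not_installed("ChemmineR")
  sdfLines <- c(
    "mol1", "  toy", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.2000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  1  3  1  0  0  0  0",
    "M  END",
    ">  <COMSIA_W_E>",
    "0.5 -0.2 0.1", "",
    "$$$$")
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdfLines, tmp)
  mols <- readMoleculeSDF(tmp)
  at <- atoms(mols[[1]])
  expect_equal(at$charge, c(0.5, -0.2, 0.1))       # tag override
  expect_true(at$donor[1])                          # N bearing an H
  expect_false(at$donor[2])
  expect_true(at$acceptor[1])
  expect_equal(at$steric[2], 1.7^3, tolerance = 1e-12)
})
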