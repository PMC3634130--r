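# PDB I/O, Kabsch superposition, rigid transforms, Calpha geometry.

test_that("fixed-column PDB parsing honours coordinates, altloc and MODEL", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  s <- readPDB(f)
  expect_identical(nrow(atomTable(s)), 1L)
  expect_equal(unname(atomCoords(s)[1, ]), c(1, 2, 3))

  # altloc: keep blank or A only
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "END"), f)
  s <- readPDB(f)
  expect_identical(nrow(atomTable(s)), 1L)
  expect_equal(atomTable(s)$x, 1)

  # first MODEL only
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       5.000   5.000   5.000  1.00  0.00           C",
    "ENDMDL"), f)
  expect_identical(nrow(atomTable(readPDB(f))), 1L)
  expect_equal(readPDB(f)@atoms$x, 1)

  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.0x0   2.000   3.000  1.00  0.00           C"),
    f)
  expect_error(readPDB(f), "line 1")
  writeLines("REMARK nothing here", f)
  expect_error(readPDB(f), "no ATOM")
})

test_that("PDB round trip preserves identity fields and coordinates", {
  bundle <- makeBundle(bundleSpec(nHelices = 3L, residuesPerHelix = 8L,
                                  seed = 5))
  f <- tempfile(fileext = ".pdb")
  writePDB(bundle$structure, f)
  back <- readPDB(f)
  a0 <- atomTable(bundle$structure); a1 <- atomTable(back)
  expect_identical(nrow(a1), nrow(a0))
  for (col in c("name", "resname", "chain", "resno", "kind", "element"))
    expect_identical(a1[[col]], a0[[col]])
  expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                    as.matrix(a0[, c("x", "y", "z")]))), 1e-3)

  # independent parser agrees on the written file
  pdb <- bio3d::read.pdb(f)
  expect_identical(nrow(pdb$atom), nrow(a0))
  expect_equal(pdb$atom$x, a0$x, tolerance = 1e-3)
  expect_identical(pdb$atom$resno, a0$resno)
})

test_that("Kabsch superposition recovers exact and noisy transforms", {
  set.seed(91)
  ref <- matrix(rnorm(60, sd = 4), 20, 3)

  fit <- kabschSuperpose(ref, ref)
  expect_equal(transformRotation(fit$transform), diag(3), tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)

  # mobile = reference translated by (5, 0, 0): recover (-5, 0, 0)
  fit <- kabschSuperpose(sweep(ref, 2, c(5, 0, 0), "+"), ref)
  expect_equal(transformTranslation(fit$transform), c(-5, 0, 0),
               tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)

  # noisy instances: never worse than the quaternion oracle; det +1
  for (k in 1:20) {
    R <- randomRotationMatrix()
    mob <- ref %*% t(R) + matrix(rnorm(60, sd = 0.1), 20, 3)
    fit <- kabschSuperpose(mob, ref)
    horn <- hornSuperpose(mob, ref)
    expect_lte(fit$rmsd, horn$rmsd + 1e-6)
    expect_equal(det(transformRotation(fit$transform)), 1, tolerance = 1e-9)
    # rmsd invariant under rigid pre-transformation of the mobile set
    pre <- sweep(mob %*% t(randomRotationMatrix()), 2, rnorm(3, sd = 10), "+")
    expect_equal(kabschSuperpose(pre, ref)$rmsd, fit$rmsd, tolerance = 1e-9)
  }

  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabschSuperpose(line, line), "collinear")
  expect_error(kabschSuperpose(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("rigid transforms preserve all pairwise distances", {
  idt <- rigidTransform()
  x <- matrix(rnorm(30), 10, 3)
  expect_identical(applyTransform(idt, x), x)

  # 90 degree rotation about z maps basis vectors analytically
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  tr <- rigidTransform(Rz, c(0, 0, 0))
  expect_equal(applyTransform(tr, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(applyTransform(tr, c(0, 1, 0)), c(-1, 0, 0), tolerance = 1e-12)

  set.seed(101)
  for (k in 1:10) {
    tr <- rigidTransform(randomRotationMatrix(), rnorm(3, sd = 8))
    y <- applyTransform(tr, x)
    expect_equal(as.matrix(dist(y)), as.matrix(dist(x)), tolerance = 1e-9)
  }

  expect_error(rigidTransform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigidTransform(refl, c(0, 0, 0)), "determinant")
})

test_that("correspondence superposition drops unusable pairs and fits Ca", {
  bundle <- makeBundle(bundleSpec(seed = 7))
  s <- bundle$structure

  # renumbered copy with offset correspondence superposes exactly
  shifted <- atomTable(s)
  shifted$resno <- shifted$resno + 100L
  s2 <- toyStructure(shifted, id = "shifted")
  pairs <- data.frame(mobile = unique(shifted$resno),
                      reference = unique(atomTable(s)$resno))
  fit <- superposeByCorrespondence(s2, s, pairs)
  expect_lt(fit$rmsd, 1e-9)
  expect_identical(fit$nUsed, 175L)

  # ensemble member at the design noise level lands in the expected band
  ens <- plantLigandEnsemble(bundle, plantedPocket(placeablePositions(
    bundle, zWindow = 8)[1:9]), nStructures = 3, noiseSigma = 0.3,
    seed = 13)
  fit <- superposeByCorrespondence(ens$structures[[1]], s)
  expect_gt(fit$rmsd, 0.2)
  expect_lt(fit$rmsd, 0.45)

  expect_error(superposeByCorrespondence(s2, s, pairs[1:2, ]),
               "fewer than 3")
})

test_that("maximum pairwise Calpha distance matches the all-pairs loop", {
  rows <- rbind(toyResidueAtoms(1, c(0, 0, 0)),
                toyResidueAtoms(2, c(10, 0, 0)))
  s <- toyStructure(rows)
  expect_equal(maxPairwiseCaDistance(s, c(1, 2)), 10)
  expect_equal(maxPairwiseCaDistance(s, 1), 0)
  expect_error(maxPairwiseCaDistance(s, c(1, 5)), "residue 5")

  bundle <- makeBundle(bundleSpec(seed = 3))
  ca <- atomTable(bundle$structure)
  ca <- ca[ca$name == "CA", ]
  set.seed(111)
  for (k in 1:10) {
    sel <- sample(ca$resno, 9)
    pts <- as.matrix(ca[match(sel, ca$resno), c("x", "y", "z")])
    brute <- 0
    for (i in 1:8) for (j in (i + 1):9)
      brute <- max(brute, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    expect_equal(maxPairwiseCaDistance(bundle$structure, sel), brute,
                 tolerance = 1e-12)
  }
})
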