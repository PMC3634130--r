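# Contact detection, ligand transfer across an ensemble, frequency
# aggregation, consensus site, annotation, compactness.

ligandRow <- function(xyz, name = "C1") {
  data.frame(name = name, resname = "LIG",
             x = xyz[1], y = xyz[2], z = xyz[3], element = "C")
}

test_that("side-chain contact detection applies the cutoff and glycine rule", {
  # CB of residue 119 at (1.5, 0, 0); ligand atom 4.0 A beyond it
  s <- toyStructure(toyResidueAtoms(119, c(0, 0, 0)))
  lig <- ligandRow(c(5.5, 0, 0))
  expect_identical(detectContacts(s, lig, cutoff = 4.5)$positions, 119L)
  expect_identical(detectContacts(s, lig, cutoff = 3.5)$positions,
                   integer(0))

  # glycine has no side-chain atoms, so it can never contact
  gly <- toyResidueAtoms(7, c(0, 0, 0), resname = "GLY")
  gly <- gly[gly$name == "CA", ]
  sg <- toyStructure(gly)
  expect_identical(detectContacts(sg, ligandRow(c(0.5, 0, 0)))$positions,
                   integer(0))
  # ... unless whole-residue mode is requested
  expect_identical(
    detectContacts(sg, ligandRow(c(0.5, 0, 0)), wholeResidue = TRUE)$positions,
    7L)

  expect_error(detectContacts(s, lig[0, ]), "empty ligand")
})

test_that("contact detection equals the brute-force scan; cutoff monotone", {
  set.seed(121)
  bundle <- makeBundle(bundleSpec(nHelices = 4L, residuesPerHelix = 10L,
                                  seed = 9))
  s <- bundle$structure
  for (k in 1:20) {
    lig <- as.data.frame(matrix(rnorm(15, sd = 6), 5, 3))
    names(lig) <- c("x", "y", "z")
    cs <- detectContacts(s, lig, cutoff = 4.5)
    expect_identical(cs$positions, bruteContacts(s, lig, 4.5))
    # monotonicity in the cutoff
    expect_true(all(detectContacts(s, lig, cutoff = 3.5)$positions %in%
                      cs$positions))
    expect_true(all(cs$positions %in%
                      detectContacts(s, lig, cutoff = 6)$positions))
  }
})

test_that("ensemble mapping transfers ligands and honours skip policy", {
  bundle <- makeBundle(bundleSpec(seed = 2))
  pocket <- plantedPocket(placeablePositions(bundle, zWindow = 8)[1:9])
  ens <- plantLigandEnsemble(bundle, pocket, nStructures = 6, seed = 77)

  # the reference model with its own planted ligand: identity superposition
  ref <- bundle$structure
  member <- ens$structures[[1]]
  sets <- mapAndDetect(list(member), ref)
  expect_identical(sets[[1]]$positions, ens$truth[[1]])

  # a member whose only HETATMs are waters is skipped, total decremented
  wat <- atomTable(member)
  wat$resname[wat$kind == "HETATM"] <- "HOH"
  watS <- toyStructure(wat, id = "watery")
  expect_warning(sets <- mapAndDetect(list(member, watS), ref),
                 "no ligand")
  expect_length(sets, 1L)
  expect_identical(aggregateFrequency(sets)@table$total[1], 1L)
})

test_that("frequency aggregation bins on the published thresholds", {
  mk <- function(n, pos) lapply(seq_len(n), function(i)
    contactSet(paste0("s", i), "LIG", if (i <= pos) 42L else integer(0)))
  t1 <- as.data.frame(aggregateFrequency(mk(22, 20)))
  expect_equal(t1$frequency[t1$position == 42], 20 / 22, tolerance = 1e-12)
  expect_identical(t1$bin[t1$position == 42], "high")

  t2 <- as.data.frame(aggregateFrequency(mk(22, 11)))
  expect_identical(t2$bin[t2$position == 42], "mid")

  z <- as.data.frame(aggregateFrequency(mk(4, 0), positions = 42L))
  expect_identical(z$bin[z$position == 42], "none")
  expect_equal(z$frequency[z$position == 42], 0)

  # boundary semantics: exactly 0.75 and 0.25 fall in the mid bin
  t3 <- as.data.frame(aggregateFrequency(mk(4, 3)))
  expect_identical(t3$bin[t3$position == 42], "mid")
  t4 <- as.data.frame(aggregateFrequency(mk(4, 1)))
  expect_identical(t4$bin[t4$position == 42], "mid")

  # order invariance and bin partition
  sets <- mk(10, 7)
  perm <- sample(sets)
  expect_identical(as.data.frame(aggregateFrequency(perm)),
                   as.data.frame(aggregateFrequency(sets)))
  tab <- as.data.frame(aggregateFrequency(sets))
  expect_true(all(tab$bin[tab$count > 0] %in% c("high", "mid", "low")))
})

test_that("consensus site is the sorted high bin", {
  sets <- c(
    lapply(1:19, function(i) contactSet(paste0("s", i), "L", c(5L, 9L, 2L))),
    lapply(20:25, function(i) contactSet(paste0("s", i), "L", 9L)))
  tab <- aggregateFrequency(sets)
  expect_identical(consensusSite(tab), c(2L, 5L, 9L))   # 19/25 = 0.76 edge

  none <- aggregateFrequency(list(contactSet("s", "L", integer(0))),
                             positions = c(3L, 8L))
  expect_identical(consensusSite(none), integer(0))
})

test_that("B-factor annotation encodes per-residue values and round-trips", {
  rows <- rbind(toyResidueAtoms(1, c(0, 0, 0)),
                toyResidueAtoms(2, c(8, 0, 0)),
                toyResidueAtoms(3, c(16, 0, 0)))
  s <- toyStructure(rows)
  sets <- lapply(1:10, function(i)
    contactSet(paste0("s", i), "L", if (i <= 10) 1L else integer(0)))
  sets[[1]]$positions <- c(1L, 2L)   # residue 2 at frequency 0.1
  tab <- aggregateFrequency(sets)
  f <- tempfile(fileext = ".pdb")
  ann <- annotateStructure(s, tab, path = f)
  a <- atomTable(ann)
  expect_true(all(a$bfactor[a$resno == 1] == 100))
  expect_true(all(a$bfactor[a$resno == 3] == 0))
  back <- readPDB(f)
  expect_equal(atomTable(back)$bfactor, a$bfactor, tolerance = 0.01)

  # conservation variant uses the profile scores
  prof <- data.frame(position = c(1, 2, 3), score = c(1, 0.5, NA))
  ann2 <- annotateStructure(s, profile = prof, what = "conservation",
                            path = f)
  a2 <- atomTable(ann2)
  expect_true(all(a2$bfactor[a2$resno == 2] == 50))
  expect_true(all(a2$bfactor[a2$resno == 3] == 0))
})

test_that("compactness check reports the span against 16 Angstrom", {
  rows <- rbind(toyResidueAtoms(1, c(0, 0, 0)),
                toyResidueAtoms(2, c(10, 0, 0)),
                toyResidueAtoms(3, c(20, 0, 0)))
  s <- toyStructure(rows)
  cc <- compactnessCheck(s, c(1, 2))
  expect_equal(cc$maxDistance, 10)
  expect_true(cc$within)
  cc2 <- compactnessCheck(s, c(1, 3))
  expect_equal(cc2$maxDistance, 20)
  expect_false(cc2$within)
})
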