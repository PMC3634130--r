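# Ground-truth generators: bundle geometry, planted pockets, simulated
# families.

test_that("ideal bundles have helix geometry and are seed-deterministic", {
  spec <- bundleSpec(seed = 4)
  b <- makeBundle(spec)
  a <- atomTable(b$structure)
  ca <- a[a$name == "CA", ]
  m <- spec$residuesPerHelix
  # consecutive Calpha spacing within each helix
  for (h in 0:(spec$nHelices - 1)) {
    idx <- h * m + seq_len(m)
    pts <- as.matrix(ca[match(idx, ca$resno), c("x", "y", "z")])
    d <- sqrt(rowSums((pts[-1, ] - pts[-m, ])^2))
    expect_true(all(abs(d - 3.8) <= 0.1))
    # helix axis parallel to z: leading principal direction of the Ca trace
    pc <- prcomp(pts)$rotation[, 1]
    expect_gt(abs(pc[3]), 0.95)
  }
  # identity reference map, full residue coverage
  expect_identical(b$refMap$ref, b$refMap$resno)
  expect_identical(sort(unique(a$resno)), 1:175)

  b2 <- makeBundle(bundleSpec(seed = 4))
  expect_identical(atomTable(b2$structure), a)
  b3 <- makeBundle(bundleSpec(seed = 5))
  expect_false(identical(b3$sequence, b$sequence))
})

test_that("planted ensembles honour their contact contract exactly", {
  b <- makeBundle(bundleSpec(seed = 6))
  inv <- placeablePositions(b, zWindow = 8)
  picks <- inv[seq_len(9)]

  # deterministic limit: no noise, every member contacts the full pocket
  ens0 <- plantLigandEnsemble(
    b, plantedPocket(picks, highFraction = 1, decoyFraction = 0),
    nStructures = 4, noiseSigma = 0, seed = 8)
  for (tr in ens0$truth)
    expect_identical(tr, sort(as.integer(picks)))

  # ground truth is self-consistent with contact detection at the cutoff
  ens <- plantLigandEnsemble(b, plantedPocket(picks), nStructures = 8,
                             seed = 9)
  for (j in seq_along(ens$structures)) {
    cs <- detectContacts(ens$structures[[j]],
                         ligandAtoms(ens$structures[[j]]), cutoff = 4.5)
    expect_identical(cs$positions, ens$truth[[j]])
  }

  # realized contact fractions sit inside binomial 99% bounds
  ens22 <- plantLigandEnsemble(b, plantedPocket(picks), nStructures = 22,
                               seed = 10)
  counts <- table(factor(unlist(ens22$truth), levels = sort(picks)))
  for (ct in as.integer(counts)) {
    expect_gte(ct, qbinom(0.005, 22, 0.9))
    expect_lte(ct, qbinom(0.995, 22, 0.9))
  }
  others <- setdiff(unlist(ens22$truth), picks)
  if (length(others)) {
    oc <- table(unlist(lapply(ens22$truth, intersect, others)))
    expect_lte(max(as.integer(oc)), qbinom(0.995, 22, 0.1))
  }

  # determinism and seed sensitivity
  ensA <- plantLigandEnsemble(b, plantedPocket(picks), nStructures = 4,
                              seed = 11)
  ensB <- plantLigandEnsemble(b, plantedPocket(picks), nStructures = 4,
                              seed = 11)
  expect_identical(lapply(ensA$structures, atomTable),
                   lapply(ensB$structures, atomTable))
  ensC <- plantLigandEnsemble(b, plantedPocket(picks), nStructures = 4,
                              seed = 12)
  expect_false(identical(atomTable(ensA$structures[[1]]),
                         atomTable(ensC$structures[[1]])))

  # infeasible pockets are refused: glycine (or any side-chain-free or
  # buried position) cannot host a planted contact
  seqv <- b$sequence
  outside <- setdiff(as.integer(names(seqv)), placeablePositions(b))
  expect_error(
    plantLigandEnsemble(b, plantedPocket(c(picks[1:8], outside[1])),
                        nStructures = 4, seed = 1),
    "infeasible")
})

test_that("simulated families carry their planted signals", {
  fam <- simulateFamily(familySpec(nLeaves = 30, seed = 14))
  # planted invariant sites are perfectly conserved
  pr <- conservationProfile(fam$alignment)
  expect_identical(pr$score[fam$spec$invariantSites],
                   rep(1, length(fam$spec$invariantSites)))
  # ligands are scaffold-true nonapeptides by construction
  expect_true(all(vapply(ligands(fam$data), function(p)
    validateNonapeptide(p)$valid, logical(1))))
  # planted covarying pair is a perfect identity-mode association
  res <- covariationStatistic(fam$data, 98, 8, mode = "identity",
                              nPermutations = 99, seed = 2)
  expect_true(res$status == "uninformative" || res$statistic == 1)

  # determinism
  fam2 <- simulateFamily(familySpec(nLeaves = 30, seed = 14))
  expect_identical(alnSequences(fam2$alignment),
                   alnSequences(fam$alignment))

  # indel mode produces truncated leaves that the coverage filter catches
  famI <- simulateFamily(familySpec(nLeaves = 30, indelMode = TRUE,
                                    truncateFraction = 0.2, seed = 15))
  f <- filterIncomplete(famI$alignment, 0.8)
  expect_gt(length(f$excluded), 0)
})

test_that("trees inferred from simulated families match the generator", {
  # internal branches bounded away from zero so every split carries
  # resolvable signal at this sequence length
  ok <- 0L
  for (r in 1:100) {
    tr <- consite:::withSeed(999L + r,
      ape::rtree(12, br = function(k) runif(k, 0.15, 0.4)))
    fam <- simulateFamily(familySpec(nLeaves = 12, tree = tr,
                                     receptorLength = 500, rate = 0.25,
                                     invariantSites = integer(0),
                                     covaryingPairs = list(), seed = 200 + r))
    d <- pairwiseDistances(fam$alignment)
    nj <- neighborJoining(d)
    if (phangorn::RF.dist(nj, fam$tree) == 0) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("planted-column sampling matches its frequency spec", {
  planted <- list(setNames(c(0.6, 0.4), c("K", "E")),
                  setNames(c(0.25, 0.25, 0.5), c("A", "G", "T")))
  aln <- samplePlantedColumns(500, planted, seed = 3)
  expect_identical(length(alnSequences(aln)), 500L)
  pfm <- buildPFM(aln, 1:2)
  expect_lt(max(abs(pfm$frequencies[c("K", "E"), 1] - planted[[1]])), 0.05)
  aln2 <- samplePlantedColumns(500, planted, seed = 3)
  expect_identical(alnSequences(aln2), alnSequences(aln))
})
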