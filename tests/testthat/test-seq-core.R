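# Sequence data model: FASTA I/O, reference numbering, scaffold and
# completeness rules.

test_that("FASTA parsing, writing and round trips preserve records", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "CYIQ"), f)
  expect_identical(readFasta(f), c(a = "CYIQ"))

  writeLines(c(">a", "CYIQ", ">b", "CY", "FQ"), f)
  got <- readFasta(f)
  expect_identical(names(got), c("a", "b"))
  expect_identical(unname(got[2]), "CYFQ")

  # round-trip property over random records, wrapped lines
  set.seed(11)
  recs <- setNames(vapply(1:12, function(i)
    randPeptide(sample(5:150, 1)), ""), paste0("s", 1:12))
  writeFasta(recs, f, width = 17L)
  expect_identical(readFasta(f), recs)

  writeLines(character(), f)
  expect_error(readFasta(f), "empty")
  writeLines(c(">a", "CYIQ", ">a", "CYFQ"), f)
  expect_error(readFasta(f), "duplicate.*a")
  writeLines(c(">a", "CYBZ"), f)
  expect_error(readFasta(f), "invalid residue")
})

test_that("reference numbering maps columns and residues both ways", {
  aln <- referenceAlignment(c(ref = "CYIQ", o = "CAFQ"), "ref")
  expect_identical(columnToRef(aln), 1:4)
  expect_identical(refToColumn(aln), 1:4)

  aln <- referenceAlignment(c(ref = "C-YI", o = "CAY-"), "ref")
  expect_identical(columnToRef(aln), c(1L, NA, 2L, 3L))
  expect_identical(refToColumn(aln), c(1L, 3L, 4L))

  # random gapped references vs the brute-force scan oracle
  set.seed(21)
  for (k in 1:25) {
    width <- sample(10:60, 1)
    chars <- sample(c(AAS, "-"), width, replace = TRUE, prob = c(rep(1, 20), 6))
    refSeq <- paste(chars, collapse = "")
    if (!grepl("[A-Z]", refSeq)) next
    aln <- referenceAlignment(c(r = refSeq, q = randPeptide(width)), "r")
    expect_identical(columnToRef(aln), bruteReferenceMap(refSeq))
    # inverse-map identity on every reference position
    expect_identical(columnToRef(aln)[refToColumn(aln)],
                     seq_along(refToColumn(aln)))
  }

  expect_error(referenceAlignment(c(a = "CY", b = "CF"), "zz"), "absent")
  expect_error(referenceAlignment(c(a = "CY", b = "CFA"), "a"), "ragged")
})

test_that("nonapeptide scaffold validation reports each violated rule", {
  expect_true(validateNonapeptide(canonicalLigands()[["oxytocin"]])$valid)
  eleven <- validateNonapeptide("CFIRNCPIGAG")   # undecapeptide
  expect_false(eleven$valid)
  expect_identical(eleven$violations, "length")
  mut <- validateNonapeptide("CYIQNCALG")        # Pro7 -> Ala
  expect_false(mut$valid)
  expect_identical(mut$violations, "position 7")
  xs <- validateNonapeptide("XYIQNCPLG")         # X never satisfies Cys1
  expect_false(xs$valid)
})

test_that("hamming distance is the mismatch count and a metric", {
  lig <- canonicalLigands()
  expect_identical(hammingDistance(lig[["oxytocin"]], lig[["vasopressin"]]),
                   2L)
  expect_identical(hammingDistance(lig[["oxytocin"]], lig[["oxytocin"]]), 0L)
  expect_error(hammingDistance("CYIQ", "CYIQN"), "unequal")

  set.seed(31)
  for (k in 1:20) {
    n <- sample(4:30, 1)
    a <- randPeptide(n); b <- randPeptide(n); c <- randPeptide(n)
    # definitional loop oracle
    loop <- sum(vapply(seq_len(n), function(i)
      substr(a, i, i) != substr(b, i, i), logical(1)))
    expect_identical(hammingDistance(a, b), as.integer(loop))
    # metric properties
    expect_identical(hammingDistance(a, b), hammingDistance(b, a))
    expect_identical(hammingDistance(a, a), 0L)
    expect_lte(hammingDistance(a, b),
               hammingDistance(a, c) + hammingDistance(c, b))
  }
})

test_that("position frequency matrices recover column compositions", {
  one <- referenceAlignment(c(r = "CYIQ"), "r")
  pfm <- buildPFM(one, 1:4)
  expect_equal(pfm$frequencies["C", "1"], 1)
  expect_equal(pfm$frequencies["Q", "4"], 1)

  four <- referenceAlignment(
    c(r = "D", a = "D", b = "D", c = "E"), "r")
  pfm <- buildPFM(four, 1L)
  expect_equal(pfm$frequencies["D", "1"], 0.75)
  expect_equal(pfm$frequencies["E", "1"], 0.25)

  # fractions sum to one over non-gap characters; gaps tracked separately
  gapped <- referenceAlignment(
    c(r = "DK", a = "-K", b = "EK", c = "DR"), "r")
  pfm <- buildPFM(gapped, 1:2)
  expect_equal(colSums(pfm$frequencies, na.rm = TRUE),
               setNames(c(1, 1), 1:2), tolerance = 1e-9)
  expect_equal(unname(pfm$gapFraction["1"]), 0.25)

  # on sampled families the PFM must equal the exact column tabulation
  planted <- list(
    setNames(c(0.70, 0.20, 0.10), c("L", "I", "V")),
    setNames(c(0.50, 0.50), c("D", "E")),
    setNames(1, "W"))
  aln <- samplePlantedColumns(500, planted, seed = 77)
  pfm <- buildPFM(aln, 1:3)
  chars <- strsplit(unname(alnSequences(aln)), "")
  for (k in 1:3) {
    col <- vapply(chars, `[[`, "", k)
    for (res in names(planted[[k]]))
      expect_equal(unname(pfm$frequencies[res, k]), mean(col == res),
                   tolerance = 1e-12)
  }
  expect_equal(unname(pfm$frequencies["W", "3"]), 1)

  expect_error(buildPFM(one, 9L), "outside")
})

test_that("completeness filter partitions by reference coverage", {
  aln <- referenceAlignment(
    c(r = "CYIQNCPLGW",
      full = "CYFQNCPRGW",
      half = "CYFQN-----",
      most = "CYFQNCPR-W"), "r")
  f <- filterIncomplete(aln, minCoverage = 0.8)
  expect_identical(f$kept, c("r", "full", "most"))
  expect_identical(f$excluded, "half")

  # random truncations vs per-sequence counting; partition invariants
  set.seed(41)
  for (k in 1:10) {
    n <- 12; L <- 40
    seqs <- vapply(1:n, function(i) {
      s <- strsplit(randPeptide(L), "")[[1]]
      drop <- sample(0:(L - 1), 1)
      if (drop > 0) s[seq_len(drop)] <- "-"
      paste(s, collapse = "")
    }, "")
    names(seqs) <- paste0("s", 1:n)
    seqs[1] <- randPeptide(L)   # complete reference
    aln <- referenceAlignment(seqs, "s1")
    f <- filterIncomplete(aln, 0.7)
    cov <- vapply(seqs, function(s)
      mean(strsplit(s, "")[[1]] != "-"), 0)
    expect_identical(f$kept, names(seqs)[cov >= 0.7])
    expect_identical(f$excluded, names(seqs)[cov < 0.7])
    expect_setequal(c(f$kept, f$excluded), names(seqs))
    # invariant to input order
    perm <- sample(n)
    f2 <- filterIncomplete(referenceAlignment(seqs[perm], "s1"), 0.7)
    expect_setequal(f2$kept, f$kept)
  }
})
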