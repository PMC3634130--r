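## synthetic_data (sequence half): receptor/ligand families simulated on a
## tree with planted conservation and covariation, plus an i.i.d.
## planted-frequency column sampler for calibration work.

#' Specification of a simulated receptor/ligand family
#'
#' Receptor sequences evolve along a tree by per-site substitution; ligand
#' nonapeptides co-evolve on the variable scaffold positions (2--5, 8).
#' Invariant receptor sites have substitution rate zero; covarying pairs
#' are enforced at the leaves by rewriting the ligand position from the
#' receptor position through a deterministic residue mapping.
#'
#' @param nLeaves number of receptor-ligand pairs (used when \code{tree} is
#'   \code{NULL}); the default mirrors a curated receptor-family set of 69
#'   entries.
#' @param tree optional \code{ape::phylo} generating tree; \code{NULL}
#'   draws a random topology with uniform branch lengths under \code{seed}.
#' @param receptorLength root receptor length (ungapped).
#' @param rootReceptor optional explicit root sequence.
#' @param rootLigand root nonapeptide (must pass the scaffold check).
#' @param rate expected substitutions per variable site per unit branch
#'   length.
#' @param invariantSites receptor positions with rate zero (planted
#'   full conservation).
#' @param covaryingPairs list of \code{list(receptor =, ligand =, map =)}
#'   entries; \code{map} is \code{NULL} for the identity mapping or a named
#'   character vector residue -> residue.  Ligand positions must be among
#'   the variable scaffold positions; receptor positions must not be
#'   invariant.
#' @param indelMode also truncate a fraction of leaves (gap prefix/suffix)
#'   to exercise coverage filtering; off by default.
#' @param truncateFraction fraction of leaves truncated in indel mode.
#' @param seed RNG seed.
#' @return list of class \code{FamilySpec}.
#' @export
familySpec <- function(nLeaves = 69L, tree = NULL, receptorLength = 120L,
                       rootReceptor = NULL, rootLigand = "CYIQNCPLG",
                       rate = 0.5, invariantSites = c(34L, 85L),
                       covaryingPairs = list(list(receptor = 98L,
                                                  ligand = 8L, map = NULL)),
                       indelMode = FALSE, truncateFraction = 0.1,
                       seed = 1L) {
  stopifnot(is.null(tree) || inherits(tree, "phylo"),
            receptorLength >= 1L, rate >= 0)
  if (!validateNonapeptide(rootLigand)$valid)
    stop("root ligand violates the nonapeptide scaffold")
  invariantSites <- as.integer(invariantSites)
  for (cp in covaryingPairs) {
    if (cp$ligand %in% c(1L, 6L, 7L, 9L))
      stop("covarying ligand positions must be scaffold-variable (2-5, 8)")
    if (cp$receptor %in% invariantSites)
      stop("covarying receptor position ", cp$receptor, " is invariant")
    if (cp$receptor > receptorLength)
      stop("covarying receptor position beyond receptor length")
  }
  if (any(invariantSites < 1L | invariantSites > receptorLength))
    stop("invariant sites outside the receptor")
  structure(list(nLeaves = as.integer(nLeaves), tree = tree,
                 receptorLength = as.integer(receptorLength),
                 rootReceptor = rootReceptor, rootLigand = rootLigand,
                 rate = rate, invariantSites = invariantSites,
                 covaryingPairs = covaryingPairs, indelMode = indelMode,
                 truncateFraction = truncateFraction,
                 seed = as.integer(seed)),
            class = "FamilySpec")
}

# substitution proposal: likelier to propose physicochemically similar
# residues (normalized similarity as log-weight)
.proposalWeights <- function(beta = 2) {
  s <- residueSimilarity()
  w <- exp(beta * s)
  diag(w) <- 0
  sweep(w, 1L, rowSums(w), "/")
}

.mutateSites <- function(chars, rates, bl, weights) {
  p <- 1 - exp(-rates * bl)
  hit <- which(runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(AA20, 1L, prob = weights[chars[i], ])
  }
  chars
}

#' Simulate a receptor/ligand family on a tree
#'
#' See [familySpec()] for the model.  The alignment is gap-free by
#' construction (reference numbering is then the identity), unless
#' \code{indelMode} truncates some leaves.
#'
#' @param spec a [familySpec()].
#' @return list with \code{data} (a [PairedDataset-class]),
#'   \code{alignment} (the receptor [ReferenceAlignment-class]),
#'   \code{tree} (the generating tree, unrooted) and \code{spec}.
#' @export
simulateFamily <- function(spec = familySpec()) {
  stopifnot(inherits(spec, "FamilySpec"))
  weights <- .proposalWeights()
  withSeed(spec$seed, {
    tree <- spec$tree %||% ape::rtree(spec$nLeaves,
                                      br = function(n) runif(n, 0.05, 0.5))
    tree$tip.label <- sprintf("R%03d", seq_along(tree$tip.label))
    L <- spec$receptorLength
    root <- spec$rootReceptor %||%
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    root <- asSequenceVector(root, "root receptor")
    if (nchar(root) != L) stop("root receptor length mismatch")
    recRates <- rep(spec$rate, L)
    recRates[spec$invariantSites] <- 0
    ligVar <- c(2L, 3L, 4L, 5L, 8L)
    ligRates <- rep(0, 9L); ligRates[ligVar] <- spec$rate

    ntip <- length(tree$tip.label)
    rootNode <- ntip + 1L
    nNode <- ntip + tree$Nnode
    recSeq <- vector("list", nNode); ligSeq <- vector("list", nNode)
    recSeq[[rootNode]] <- strsplit(root, "")[[1L]]
    ligSeq[[rootNode]] <- strsplit(spec$rootLigand, "")[[1L]]
    # preorder edge walk
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
      bl <- ord$edge.length[e]
      recSeq[[child]] <- .mutateSites(recSeq[[par]], recRates, bl, weights)
      ligSeq[[child]] <- .mutateSites(ligSeq[[par]], ligRates, bl, weights)
    }
    recLeaf <- vapply(seq_len(ntip), function(i)
      paste(recSeq[[i]], collapse = ""), "")
    ligLeaf <- vapply(seq_len(ntip), function(i) {
      l <- ligSeq[[i]]
      for (cp in spec$covaryingPairs) {
        r <- recSeq[[i]][cp$receptor]
        l[cp$ligand] <- if (is.null(cp$map)) r else unname(cp$map[[r]])
      }
      paste(l, collapse = "")
    }, "")
    names(recLeaf) <- names(ligLeaf) <- tree$tip.label

    if (spec$indelMode) {
      nTrunc <- max(1L, round(spec$truncateFraction * ntip))
      victims <- sample(seq_len(ntip), nTrunc)
      for (v in victims) {
        keepFrom <- sample(seq(floor(L * 0.3), floor(L * 0.6)), 1L)
        side <- sample(c("head", "tail"), 1L)
        s <- strsplit(recLeaf[v], "")[[1L]]
        if (side == "head") s[seq_len(keepFrom)] <- GAP
        else s[seq(L - keepFrom + 1L, L)] <- GAP
        recLeaf[v] <- paste(s, collapse = "")
      }
      # reference must stay complete
      if (1L %in% victims) recLeaf[1L] <- paste(recSeq[[1L]], collapse = "")
    }
    aln <- referenceAlignment(recLeaf, referenceId = names(recLeaf)[1L])
    list(data = pairedDataset(aln, ligLeaf), alignment = aln,
         tree = ape::unroot(tree), spec = spec)
  })
}

#' Sample an alignment with planted per-column residue frequencies
#'
#' Draws \code{nSequences} gap-free sequences whose columns are i.i.d.
#' multinomial with the given residue frequencies -- the calibration input
#' for position-frequency-matrix recovery (the planted frequencies are the
#' oracle).
#'
#' @param nSequences number of sequences.
#' @param columnFrequencies list, one element per column: named numeric
#'   vector of residue frequencies (summing to 1).
#' @param seed RNG seed.
#' @return a [ReferenceAlignment-class] (first sequence is the reference;
#'   numbering is the identity since the alignment is gap-free).
#' @export
samplePlantedColumns <- function(nSequences, columnFrequencies, seed = 1L) {
  stopifnot(nSequences >= 2L, length(columnFrequencies) >= 1L)
  for (f in columnFrequencies) {
    stopifnot(!is.null(names(f)), all(names(f) %in% AA20),
              abs(sum(f) - 1) < 1e-9)
  }
  withSeed(seed, {
    cols <- lapply(columnFrequencies, function(f)
      sample(names(f), nSequences, replace = TRUE, prob = f))
    m <- do.call(cbind, cols)
    seqs <- apply(m, 1L, paste, collapse = "")
    names(seqs) <- sprintf("S%04d", seq_len(nSequences))
    referenceAlignment(seqs, referenceId = names(seqs)[1L])
  })
}
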