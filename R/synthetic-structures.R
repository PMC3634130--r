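## synthetic_data (structural half): ideal seven-helix bundles and
## ensembles with a planted ligand pocket and full ground-truth bookkeeping.

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

# side-chain pseudo-atom count per residue (glycine none, consistent with
# the side-chain contact rule); length grows with residue size
.SIDE_ATOMS <- c(G = 0L, A = 1L, S = 1L, C = 1L, T = 2L, V = 2L, P = 2L,
                 D = 2L, N = 2L, I = 3L, L = 3L, E = 3L, Q = 3L, M = 3L,
                 K = 3L, H = 3L, F = 4L, R = 4L, Y = 4L, W = 4L)
.SIDE_NAMES <- c("CB", "CG", "CD", "CE")
.SIDE_BASE <- 1.6   # CA -> CB distance, Angstrom
.SIDE_STEP <- 0.4   # spacing of further pseudo-atoms

#' Specification of a synthetic helix bundle
#'
#' Geometry of an idealized transmembrane bundle: \code{nHelices} ideal
#' alpha-helices (rise 1.5 Angstrom and twist 100 degrees per residue)
#' arranged antiparallel on a circle of radius \code{bundleRadius}, each
#' residue carrying backbone pseudo-atoms (N, CA, C, O) and 0--4 side-chain
#' pseudo-atoms extended radially from the helix axis.
#'
#' @param nHelices number of helices (>= 2).
#' @param residuesPerHelix residues per helix.
#' @param bundleRadius distance from the bundle axis to each helix axis
#'   (Angstrom).
#' @param helixRadius Calpha helix radius (Angstrom).
#' @param rise,twist helical rise (Angstrom/residue) and twist
#'   (degrees/residue).
#' @param seed RNG seed controlling the residue identities.
#' @return list of class \code{BundleSpec}.
#' @export
bundleSpec <- function(nHelices = 7L, residuesPerHelix = 25L,
                       bundleRadius = 12.5, helixRadius = 2.3,
                       rise = 1.5, twist = 100, seed = 1L) {
  stopifnot(nHelices >= 2L, residuesPerHelix >= 4L, bundleRadius > 0,
            helixRadius > 0, rise > 0, twist > 0)
  structure(list(nHelices = as.integer(nHelices),
                 residuesPerHelix = as.integer(residuesPerHelix),
                 bundleRadius = bundleRadius, helixRadius = helixRadius,
                 rise = rise, twist = twist, seed = as.integer(seed)),
            class = "BundleSpec")
}

#' Generate an idealized helix-bundle structure
#'
#' Deterministic given the spec (including its seed, which fixes the
#' residue identities).  Residues are numbered 1..N across helices in
#' order, on chain A; the reference map is the identity on the residue
#' number.  Helix phases are staggered so that inward-facing residues of
#' neighbouring helices sit at different heights, which keeps the central
#' pocket geometrically workable.
#'
#' @param spec a [bundleSpec()].
#' @return list with \code{structure} (a [PDBStructure-class]),
#'   \code{refMap} (chain/resno/ref data.frame), \code{sequence} (named
#'   one-letter vector by residue number) and \code{spec}.
#' @export
makeBundle <- function(spec = bundleSpec()) {
  stopifnot(inherits(spec, "BundleSpec"))
  H <- spec$nHelices; m <- spec$residuesPerHelix
  nRes <- H * m
  resIds <- withSeed(spec$seed,
                     sample(AA20, nRes, replace = TRUE))
  rows <- vector("list", nRes)
  serial <- 0L
  twistRad <- spec$twist * pi / 180
  for (h in seq_len(H) - 1L) {
    phi <- 2 * pi * h / H
    ctr <- c(spec$bundleRadius * cos(phi), spec$bundleRadius * sin(phi))
    dir <- if (h %% 2L == 0L) 1 else -1          # antiparallel
    alpha0 <- phi + pi + h * (40 * pi / 180)     # staggered phase
    for (i in seq_len(m)) {
      resno <- h * m + i
      aa <- resIds[resno]
      zi <- (i - (m + 1) / 2) * spec$rise * dir
      ai <- alpha0 + (i - 1L) * twistRad * dir
      u <- c(cos(ai), sin(ai))
      ca <- c(ctr + spec$helixRadius * u, zi)
      atoms <- list(
        N = c(ctr + 1.6 * c(cos(ai - 0.8), sin(ai - 0.8)), zi - 0.5 * dir),
        CA = ca,
        C = c(ctr + 1.7 * c(cos(ai + 0.8), sin(ai + 0.8)), zi + 0.5 * dir),
        O = c(ctr + 2.0 * c(cos(ai + 1.1), sin(ai + 1.1)), zi + 1.1 * dir))
      nSide <- .SIDE_ATOMS[[aa]]
      if (nSide > 0L) for (k in seq_len(nSide)) {
        atoms[[.SIDE_NAMES[k]]] <-
          c(ca[1:2] + (.SIDE_BASE + .SIDE_STEP * (k - 1)) * u, zi)
      }
      nm <- names(atoms)
      rows[[resno]] <- data.frame(
        serial = serial + seq_along(atoms),
        kind = "ATOM", name = nm, altloc = "",
        resname = AA3[[aa]], chain = "A", resno = resno, icode = "",
        x = vapply(atoms, `[[`, 0, 1L),
        y = vapply(atoms, `[[`, 0, 2L),
        z = vapply(atoms, `[[`, 0, 3L),
        occupancy = 1, bfactor = 0,
        element = substr(nm, 1L, 1L),
        stringsAsFactors = FALSE)
      serial <- serial + length(atoms)
    }
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  list(structure = methods::new("PDBStructure", id = "bundle",
                                atoms = atoms),
       refMap = data.frame(chain = "A", resno = seq_len(nRes),
                           ref = seq_len(nRes)),
       sequence = setNames(resIds, seq_len(nRes)),
       spec = spec)
}

#' Planted-pocket specification
#'
#' Ground-truth contract for a synthetic ensemble: each pocket position
#' must contact the ligand in a fraction \code{highFraction} of members
#' (above the 0.75 high-bin threshold) while every other position stays at
#' or below \code{decoyFraction} (below the 0.25 threshold).
#'
#' @param positions reference numbers of the pocket residues.
#' @param highFraction target contact fraction for pocket positions
#'   (> 0.75).
#' @param decoyFraction maximum contact fraction for non-pocket positions
#'   (< 0.25).
#' @return list of class \code{PlantedPocket}.
#' @export
plantedPocket <- function(positions, highFraction = 0.9,
                          decoyFraction = 0.1) {
  positions <- sort(unique(as.integer(positions)))
  stopifnot(length(positions) >= 1L,
            highFraction > 0.75, highFraction <= 1,
            decoyFraction >= 0, decoyFraction < 0.25)
  structure(list(positions = positions, highFraction = highFraction,
                 decoyFraction = decoyFraction), class = "PlantedPocket")
}

# per-residue side-chain geometry: tip atom and the unit direction from the
# tip toward the bundle (z) axis at the tip's height
.sideGeometry <- function(atoms) {
  side <- atoms[atoms$kind == "ATOM" & !(atoms$name %in% .BACKBONE), ,
                drop = FALSE]
  if (nrow(side) == 0L) return(NULL)
  split(side, side$resno)
}

.tipOf <- function(resAtoms) {
  as.numeric(resAtoms[nrow(resAtoms), c("x", "y", "z")])
}

.towardAxis <- function(p) {
  v <- c(-p[1L], -p[2L], 0)
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(0, 0, 1) else v / n
}

#' Positions where a ligand contact atom can be planted
#'
#' A position is placeable when it has side-chain atoms and a candidate
#' contact point (a few Angstrom inward of its side-chain tip) clears all
#' other residues' side chains by \code{cutoff + clearance}.  Pocket and
#' decoy positions for [plantLigandEnsemble()] must be placeable.
#'
#' @param bundle output of [makeBundle()].
#' @param cutoff contact cutoff that will be used downstream (Angstrom).
#' @param contactDistance preferred tip-to-ligand-atom distance; nearby
#'   alternatives are tried automatically.
#' @param clearance required margin beyond \code{cutoff} to every other
#'   residue (absorbs coordinate noise).
#' @param zWindow restrict to positions whose contact point lies within
#'   \code{[-zWindow, zWindow]} along the bundle axis -- a binding pocket
#'   occupies a vestibule, not the full membrane span.
#' @return integer vector of placeable residue numbers.
#' @export
placeablePositions <- function(bundle, cutoff = 4.5, contactDistance = 3.0,
                               clearance = 0.8, zWindow = Inf) {
  pts <- .placementPoints(bundle, cutoff, contactDistance, clearance)
  ok <- !vapply(pts, is.null, logical(1))
  ok[ok] <- vapply(pts[ok], function(p) abs(p[3L]) <= zWindow, logical(1))
  as.integer(names(pts)[ok])
}

# candidate placement point per residue (NULL when infeasible)
.placementPoints <- function(bundle, cutoff, contactDistance, clearance) {
  atoms <- atomTable(bundle$structure)
  byRes <- .sideGeometry(atoms)
  allSide <- do.call(rbind, byRes)
  sideXYZ <- as.matrix(allSide[, c("x", "y", "z")])
  sideRes <- allSide$resno
  tryDist <- contactDistance + c(0, -0.4, 0.4, -0.8, 0.8)
  need2 <- (cutoff + clearance)^2
  out <- setNames(vector("list", length(byRes)), names(byRes))
  for (nm in names(byRes)) {
    tip <- .tipOf(byRes[[nm]])
    dirIn <- .towardAxis(tip)
    resno <- byRes[[nm]]$resno[1L]
    others <- sideRes != resno
    for (dd in tryDist) {
      if (dd <= 0) next
      q <- tip + dd * dirIn
      d2 <- colSums((t(sideXYZ[others, , drop = FALSE]) - q)^2)
      if (min(d2) >= need2) { out[[nm]] <- q; break }
    }
  }
  out
}

# uniform random rotation from a random unit quaternion
.randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Generate a structure ensemble with a planted ligand pocket
#'
#' Each member is the bundle with Gaussian coordinate noise plus a
#' pseudo-ligand (HETATM residue \code{LIG}) whose atoms are placed a fixed
#' distance inward of selected side-chain tips.  For every pocket position,
#' \code{ceiling(highFraction * n)} members receive a contact atom at that
#' position; every other placeable position receives one in
#' \code{floor(decoyFraction * n)} members, so realized contact fractions
#' sit on the intended side of the 0.75 / 0.25 bin edges by construction.
#' Members are finally scattered by random rigid transforms, which the
#' mapping pipeline must undo.  Ground truth is recorded per member by a
#' direct all-pairs distance scan at \code{cutoff} in the generation frame.
#'
#' \code{noiseSigma} is the per-atom root-mean-square displacement
#' (per-coordinate standard deviation \code{noiseSigma / sqrt(3)}).
#'
#' @param bundle output of [makeBundle()] (the noiseless parent; also the
#'   natural reference model for [mapAndDetect()]).
#' @param pocket a [plantedPocket()]; all pocket positions must be
#'   placeable, else an error reports the infeasible geometry.
#' @param nStructures ensemble size (>= 2).
#' @param noiseSigma per-atom RMS displacement, Angstrom.
#' @param seed RNG seed; the ensemble is a pure function of
#'   (bundle, pocket, arguments, seed).
#' @param cutoff generation (and intended detection) contact cutoff.
#' @param contactDistance,clearance see [placeablePositions()].
#' @param ligandSpan maximum allowed spread of the planted contact points
#'   (Angstrom); pockets wider than a ligand could span are refused.
#' @return list with \code{structures} (list of [PDBStructure-class]),
#'   \code{truth} (per member, sorted integer contact positions),
#'   \code{pocket}, \code{placeable} and \code{params}.
#' @export
plantLigandEnsemble <- function(bundle, pocket, nStructures = 22L,
                                noiseSigma = 0.3, seed = 1L, cutoff = 4.5,
                                contactDistance = 3.0, clearance = 0.8,
                                ligandSpan = 25) {
  stopifnot(inherits(pocket, "PlantedPocket"), nStructures >= 2L,
            noiseSigma >= 0)
  n <- as.integer(nStructures)
  pts <- .placementPoints(bundle, cutoff, contactDistance, clearance)
  placeable <- as.integer(names(pts)[!vapply(pts, is.null, logical(1))])
  bad <- setdiff(pocket$positions, placeable)
  if (length(bad))
    stop("infeasible pocket geometry at position(s): ",
         paste(bad, collapse = ", "))
  ppts <- do.call(rbind, pts[as.character(pocket$positions)])
  if (length(pocket$positions) > 1L && max(dist(ppts)) > ligandSpan)
    stop(sprintf("pocket spans %.1f A, more than the ligand can bridge (%g A)",
                 max(dist(ppts)), ligandSpan))
  decoys <- setdiff(placeable, pocket$positions)
  kHigh <- min(n, as.integer(ceiling(pocket$highFraction * n)))
  kDecoy <- as.integer(floor(pocket$decoyFraction * n))
  if (kHigh / n <= 0.75)
    stop("highFraction too low to exceed the high bin at this ensemble size")

  atoms0 <- atomTable(bundle$structure)
  sideMask <- atoms0$kind == "ATOM" & !(atoms0$name %in% .BACKBONE)
  tipIdx <- vapply(split(which(sideMask), atoms0$resno[sideMask]),
                   function(ix) ix[length(ix)], integer(1))
  cSd <- noiseSigma / sqrt(3)

  withSeed(seed, {
    members <- lapply(pocket$positions, function(p) sample.int(n, kHigh))
    names(members) <- pocket$positions
    if (kDecoy > 0L) {
      dm <- lapply(decoys, function(p) sample.int(n, kDecoy))
      names(dm) <- decoys
      members <- c(members, dm)
    }
    planted <- lapply(seq_len(n), function(j)
      as.integer(names(members))[vapply(members, function(s) j %in% s,
                                        logical(1))])
    zTop <- max(atoms0$z) + 10

    structures <- vector("list", n)
    truth <- vector("list", n)
    for (j in seq_len(n)) {
      a <- atoms0
      if (noiseSigma > 0)
        a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
          matrix(rnorm(3L * nrow(a), sd = cSd), ncol = 3L)
      ligXYZ <- NULL
      for (p in planted[[j]]) {
        tip <- as.numeric(a[tipIdx[[as.character(p)]], c("x", "y", "z")])
        ligXYZ <- rbind(ligXYZ, tip + contactDistance * .towardAxis(tip))
      }
      if (is.null(ligXYZ))   # degenerate member: park the ligand clear of
        ligXYZ <- rbind(c(0, 0, zTop), c(0, 0, zTop + 1.4))  # everything
      lig <- data.frame(
        serial = max(a$serial) + seq_len(nrow(ligXYZ)),
        kind = "HETATM", name = paste0("C", seq_len(nrow(ligXYZ))),
        altloc = "", resname = "LIG", chain = "L", resno = 1L, icode = "",
        x = ligXYZ[, 1L], y = ligXYZ[, 2L], z = ligXYZ[, 3L],
        occupancy = 1, bfactor = 0, element = "C",
        stringsAsFactors = FALSE)
      # ground truth: direct all-pairs scan in the generation frame
      sideXYZ <- as.matrix(a[sideMask, c("x", "y", "z")])
      d2 <- outer(rowSums(sideXYZ^2), rowSums(ligXYZ^2), "+") -
        2 * sideXYZ %*% t(ligXYZ)
      hit <- rowSums(d2 <= cutoff^2 + 1e-12) > 0
      truth[[j]] <- sort(unique(a$resno[sideMask][hit]))

      all <- rbind(a, lig)
      tr <- rigidTransform(.randomRotation(), runif(3, -15, 15))
      all[, c("x", "y", "z")] <-
        applyTransform(tr, as.matrix(all[, c("x", "y", "z")]))
      structures[[j]] <- methods::new(
        "PDBStructure", id = sprintf("member_%02d", j), atoms = all)
    }
    names(truth) <- vapply(structures, structureId, "")
    list(structures = structures, truth = truth, pocket = pocket,
         placeable = placeable,
         params = list(nStructures = n, noiseSigma = noiseSigma,
                       seed = as.integer(seed), cutoff = cutoff,
                       contactDistance = contactDistance,
                       clearance = clearance, kHigh = kHigh,
                       kDecoy = kDecoy))
  })
}
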