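## pocket_map: the central computation.  Side-chain/ligand contact
## detection per structure, ligand transfer into the reference frame,
## frequency aggregation, binning, consensus site and structure annotation.

#' Default solvent/ion exclusion list
#'
#' HETATM residue names that never count as ligands (waters, common ions
#' and crystallization additives).
#' @return character vector.
#' @export
defaultLigandExclusions <- function() {
  c("HOH", "DOD", "NA", "CL", "SO4", "PO4", "GOL", "EDO")
}

#' Ligand atoms of a structure
#'
#' HETATM records whose residue name is not excluded; hydrogens dropped.
#'
#' @param x a [PDBStructure-class].
#' @param exclusions residue names to ignore.
#' @return data.frame of atom rows (possibly empty).
#' @export
ligandAtoms <- function(x, exclusions = defaultLigandExclusions()) {
  a <- atomTable(x)
  a[a$kind == "HETATM" & !(a$resname %in% exclusions) & a$element != "H", ,
    drop = FALSE]
}

# bin labels from the published colour thresholds; edges inclusive into mid
frequencyBin <- function(f, edges = c(0.25, 0.75)) {
  ifelse(f == 0, "none",
         ifelse(f > edges[2L], "high",
                ifelse(f >= edges[1L], "mid", "low")))
}

#' Build a contact set record
#'
#' @param structureId,ligandId identifiers.
#' @param positions integer reference positions (stored sorted, unique).
#' @return list of class \code{ContactSet}.
#' @export
contactSet <- function(structureId, ligandId, positions) {
  structure(list(structureId = structureId, ligandId = ligandId,
                 positions = sort(unique(as.integer(positions)))),
            class = "ContactSet")
}

#' @export
print.ContactSet <- function(x, ...) {
  cat(sprintf("ContactSet %s/%s: %d positions\n", x$structureId, x$ligandId,
              length(x$positions)))
  invisible(x)
}

# map (chain, resno) of receptor residues to reference numbers.
# refMap NULL means reference number = residue number.
.refLookup <- function(chain, resno, refMap) {
  if (is.null(refMap)) return(as.integer(resno))
  refMap$ref[match(paste(chain, resno), paste(refMap$chain, refMap$resno))]
}

#' Detect side-chain contacts between a receptor and ligand atoms
#'
#' A reference position is contacted when any of its side-chain heavy atoms
#' (Cbeta outward; glycine therefore never) lies within \code{cutoff} of
#' any ligand heavy atom.  With \code{wholeResidue = TRUE}, backbone atoms
#' count too.
#'
#' @param receptor a [PDBStructure-class].
#' @param ligandCoords data.frame of ligand atoms with columns \code{x, y,
#'   z} (heavy atoms; an \code{element} column, if present, is used to drop
#'   hydrogens) and optionally \code{resname} for the ligand id.
#' @param refMap data.frame (\code{chain}, \code{resno}, \code{ref}) mapping
#'   receptor residues to reference numbers, or \code{NULL} for identity on
#'   the residue number.  Receptor residues without a mapping are skipped
#'   (their count is reported as an attribute).
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @param wholeResidue include backbone atoms in the contact test.
#' @return a \code{ContactSet}; attribute \code{nUnmapped} counts skipped
#'   residues.
#' @export
detectContacts <- function(receptor, ligandCoords, refMap = NULL,
                           cutoff = 4.5, wholeResidue = FALSE) {
  stopifnot(methods::is(receptor, "PDBStructure"), cutoff > 0)
  if (is.data.frame(ligandCoords) && "element" %in% names(ligandCoords))
    ligandCoords <- ligandCoords[ligandCoords$element != "H", , drop = FALSE]
  if (NROW(ligandCoords) == 0L) stop("empty ligand")
  lig <- as.matrix(ligandCoords[, c("x", "y", "z")])
  a <- atomTable(receptor)
  a <- a[a$kind == "ATOM" & a$element != "H", , drop = FALSE]
  if (!wholeResidue)
    a <- a[!(a$name %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
  refs <- .refLookup(a$chain, a$resno, refMap)
  nUnmapped <- length(unique(paste(a$chain, a$resno)[is.na(refs)]))
  keep <- !is.na(refs)
  a <- a[keep, , drop = FALSE]; refs <- refs[keep]
  contacted <- integer(0)
  if (nrow(a)) {
    rec <- as.matrix(a[, c("x", "y", "z")])
    # N x M squared cross-distances
    d2 <- outer(rowSums(rec^2), rowSums(lig^2), "+") - 2 * rec %*% t(lig)
    hit <- rowSums(d2 <= cutoff^2 + 1e-12) > 0
    contacted <- unique(refs[hit])
  }
  ligId <- if ("resname" %in% names(ligandCoords) && nrow(ligandCoords))
    paste(unique(ligandCoords$resname), collapse = "+") else "LIG"
  cs <- contactSet(structureId(receptor), ligId, contacted)
  attr(cs, "nUnmapped") <- nUnmapped
  cs
}

#' Superpose an ensemble onto a reference model and detect ligand contacts
#'
#' For each ensemble structure: superpose its receptor onto the reference
#' model ([superposeByCorrespondence()]), apply the fitted transform to its
#' ligand atoms (ligand transfer), then detect contacts of the transferred
#' ligand with the reference model's side chains.  Structures without a
#' ligand after exclusion-list filtering are skipped with a warning and do
#' not count toward the ensemble total.
#'
#' With \code{crystalSide = TRUE} contacts are instead measured inside each
#' crystal frame (ligand vs its own receptor) and mapped to reference
#' numbering; the default, transfer-side analysis is the published
#' procedure.
#'
#' @param ensemble list of [PDBStructure-class] objects.
#' @param referenceModel the reference [PDBStructure-class].
#' @param pairs residue correspondence passed to
#'   [superposeByCorrespondence()] (\code{NULL}: shared numbering).
#' @param refMap reference-numbering map for the reference model (see
#'   [detectContacts()]).
#' @param cutoff,wholeResidue,exclusions see [detectContacts()] and
#'   [ligandAtoms()].
#' @param crystalSide measure contacts in the crystal frame instead.
#' @return list of \code{ContactSet} (attribute \code{superposition}: a
#'   data.frame of per-structure rmsd and pair counts).
#' @export
mapAndDetect <- function(ensemble, referenceModel, pairs = NULL,
                         refMap = NULL, cutoff = 4.5, wholeResidue = FALSE,
                         exclusions = defaultLigandExclusions(),
                         crystalSide = FALSE) {
  stopifnot(methods::is(referenceModel, "PDBStructure"))
  sets <- list(); info <- NULL
  for (s in ensemble) {
    lig <- ligandAtoms(s, exclusions)
    if (nrow(lig) == 0L) {
      warning("structure ", structureId(s),
              " has no ligand after exclusion filtering; skipped")
      next
    }
    fit <- superposeByCorrespondence(s, referenceModel, pairs)
    if (crystalSide) {
      cs <- detectContacts(s, lig, refMap = refMap, cutoff = cutoff,
                           wholeResidue = wholeResidue)
      cs$structureId <- structureId(s)
    } else {
      lig[, c("x", "y", "z")] <-
        applyTransform(fit$transform, as.matrix(lig[, c("x", "y", "z")]))
      cs <- detectContacts(referenceModel, lig, refMap = refMap,
                           cutoff = cutoff, wholeResidue = wholeResidue)
      cs$structureId <- structureId(s)
    }
    sets[[length(sets) + 1L]] <- cs
    info <- rbind(info, data.frame(structure = structureId(s),
                                   rmsd = fit$rmsd, nUsed = fit$nUsed,
                                   nDropped = fit$nDropped))
  }
  attr(sets, "superposition") <- info
  sets
}

#' Aggregate contact sets into a frequency table
#'
#' The counting unit is the structure: each contact set contributes at most
#' one count per position.  Frequencies are binned on the published scale
#' (> 0.75 high, 0.25--0.75 mid, below 0.25 low, zero none).
#'
#' @param contactSets list of \code{ContactSet}.
#' @param positions optional reference positions to force into the table
#'   (reported with zero counts when never contacted).
#' @return a [ContactFrequencyTable-class].
#' @export
aggregateFrequency <- function(contactSets, positions = NULL) {
  if (length(contactSets) == 0L) stop("no contact sets")
  total <- length(contactSets)
  counts <- table(unlist(lapply(contactSets, `[[`, "positions")))
  pos <- sort(unique(c(as.integer(names(counts)), as.integer(positions))))
  cnt <- integer(length(pos))
  cnt[match(as.integer(names(counts)), pos)] <- as.integer(counts)
  f <- cnt / total
  methods::new("ContactFrequencyTable",
               table = data.frame(position = pos, count = cnt,
                                  total = total, frequency = f,
                                  bin = frequencyBin(f)))
}

#' Consensus binding site
#'
#' The positions contacted in more than 75% of analysed structures (the
#' high bin), ascending -- the shared, core binding site of the ensemble.
#'
#' @param table a [ContactFrequencyTable-class].
#' @return sorted integer vector (possibly empty).
#' @export
consensusSite <- function(table) {
  stopifnot(methods::is(table, "ContactFrequencyTable"))
  t <- as.data.frame(table)
  sort(t$position[t$bin == "high"])
}

#' Annotate a structure with per-position values in the B-factor column
#'
#' Writes the model with either contact frequency x 100 or conservation
#' score x 100 in the temperature-factor column of every atom of each
#' residue, so structure viewers can colour by it.  Unannotated residues
#' get 0.
#'
#' @param model a [PDBStructure-class] whose residues map to reference
#'   numbers (via \code{refMap}, or identity).
#' @param table a [ContactFrequencyTable-class] (used when
#'   \code{what = "frequency"}).
#' @param profile a [conservationProfile()] data.frame (used when
#'   \code{what = "conservation"}).
#' @param path output PDB file.
#' @param what which annotation to write.
#' @param refMap see [detectContacts()].
#' @return invisibly, the annotated [PDBStructure-class].
#' @export
annotateStructure <- function(model, table = NULL, profile = NULL, path,
                              what = c("frequency", "conservation"),
                              refMap = NULL) {
  what <- match.arg(what)
  stopifnot(methods::is(model, "PDBStructure"))
  values <- if (what == "frequency") {
    stopifnot(methods::is(table, "ContactFrequencyTable"))
    t <- as.data.frame(table)
    setNames(t$frequency * 100, t$position)
  } else {
    stopifnot(is.data.frame(profile))
    ok <- !is.na(profile$score)
    setNames(profile$score[ok] * 100, profile$position[ok])
  }
  a <- atomTable(model)
  refs <- .refLookup(a$chain, a$resno, refMap)
  v <- values[as.character(refs)]
  v[is.na(v)] <- 0
  a$bfactor <- as.numeric(v)
  out <- methods::new("PDBStructure", id = structureId(model), atoms = a)
  writePDB(out, path)
  invisible(out)
}

#' Compactness of a residue selection
#'
#' Maximum pairwise Calpha distance over the selected positions, and
#' whether it falls within the 16 Angstrom span characteristic of a compact
#' transmembrane binding core.
#'
#' @param model a [PDBStructure-class].
#' @param positions residue selection, see [maxPairwiseCaDistance()].
#' @param threshold span threshold in Angstrom.
#' @return list with \code{maxDistance} and \code{within} (logical).
#' @export
compactnessCheck <- function(model, positions, threshold = 16) {
  d <- maxPairwiseCaDistance(model, positions)
  list(maxDistance = d, within = d <= threshold)
}
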