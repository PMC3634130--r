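#' Reference-numbered multiple sequence alignment
#'
#' An S4 container for a gapped protein alignment together with a
#' bidirectional map between alignment columns and the residue numbering of
#' a designated reference sequence (for the oxytocin-receptor family, the
#' human OTR).  All downstream position arguments in the package are
#' reference residue numbers, never raw column indices.
#'
#' @slot sequences named character vector of equal-length gapped sequences
#'   (upper case; alphabet: the 20 residues, \code{-} and \code{X}).
#' @slot referenceId name of the reference sequence.
#' @slot columnToRef integer vector, one entry per alignment column; the
#'   reference residue number of that column or \code{NA} where the
#'   reference carries a gap.
#' @slot refToColumn integer vector indexed by reference residue number
#'   (1..R); the alignment column holding that residue.
#'
#' @seealso [referenceAlignment()], the user-facing constructor.
#' @exportClass ReferenceAlignment
setClass("ReferenceAlignment",
  representation(
    sequences   = "character",
    referenceId = "character",
    columnToRef = "integer",
    refToColumn = "integer"
  )
)

setValidity("ReferenceAlignment", function(object) {
  s <- object@sequences
  if (length(s) == 0L) return("alignment has no sequences")
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
    return("all sequences must be named")
  if (anyDuplicated(names(s))) return("duplicate sequence ids")
  if (length(unique(nchar(s))) != 1L) return("ragged alignment")
  if (!(object@referenceId %in% names(s)))
    return(sprintf("reference '%s' absent from alignment", object@referenceId))
  if (length(object@columnToRef) != nchar(s[[1L]]))
    return("columnToRef length != alignment width")
  mapped <- object@columnToRef[!is.na(object@columnToRef)]
  if (length(mapped) != length(object@refToColumn))
    return("column/reference maps are not mutual inverses")
  if (length(mapped) && (any(diff(mapped) <= 0L) ||
      !identical(object@refToColumn[mapped],
                 which(!is.na(object@columnToRef)))))
    return("reference numbering must strictly increase with column index")
  TRUE
})

#' Rigid-body transform (proper rotation + translation)
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector (Angstrom).
#' @seealso [kabschSuperpose()], [applyTransform()]
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation is not orthonormal")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation determinant must be +1 (no reflection)")
  TRUE
})

#' Atomic structure parsed from a PDB file
#'
#' Holds ATOM/HETATM records as an atom table; residues are identified by
#' (chain, residue number, insertion code).  Ligand atoms are HETATM records
#' whose residue name is not on the solvent/ion exclusion list (see
#' [ligandAtoms()]).
#'
#' @slot id structure identifier (file stem by default).
#' @slot atoms data.frame with columns \code{serial, kind, name, altloc,
#'   resname, chain, resno, icode, x, y, z, occupancy, bfactor, element}.
#' @seealso [readPDB()], [writePDB()]
#' @exportClass PDBStructure
setClass("PDBStructure",
  representation(id = "character", atoms = "data.frame"))

.atomCols <- c("serial", "kind", "name", "altloc", "resname", "chain",
               "resno", "icode", "x", "y", "z", "occupancy", "bfactor",
               "element")

setValidity("PDBStructure", function(object) {
  a <- object@atoms
  if (!all(.atomCols %in% names(a))) return("atom table misses columns")
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(a$kind %in% c("ATOM", "HETATM"))) return("kind must be ATOM/HETATM")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  TRUE
})

#' Per-position ligand contact frequencies across an ensemble
#'
#' For every reference position, the number of analysed structures whose
#' (transferred) ligand contacts that residue's side chain, the total number
#' of structures analysed, the resulting frequency and its bin.  Bins follow
#' the published colour scale: \code{high} for frequency > 0.75, \code{mid}
#' for 0.25--0.75 inclusive, \code{low} for anything positive below 0.25 and
#' \code{none} for zero.
#'
#' @slot table data.frame with columns \code{position, count, total,
#'   frequency, bin}.
#' @seealso [aggregateFrequency()], [consensusSite()]
#' @exportClass ContactFrequencyTable
setClass("ContactFrequencyTable", representation(table = "data.frame"))

setValidity("ContactFrequencyTable", function(object) {
  t <- object@table
  need <- c("position", "count", "total", "frequency", "bin")
  if (!all(need %in% names(t))) return("frequency table misses columns")
  if (anyDuplicated(t$position)) return("duplicate positions")
  if (any(t$frequency < 0 | t$frequency > 1)) return("frequency outside [0,1]")
  expect <- frequencyBin(t$frequency)
  if (!identical(as.character(t$bin), expect))
    return("bins inconsistent with frequencies")
  TRUE
})

#' Paired receptor/ligand sequence records
#'
#' One short peptide ligand per receptor, alongside the receptor alignment.
#' Ligands that fail the nonapeptide scaffold check (Cys1, Cys6, Pro7, Gly9)
#' are kept but flagged \code{nonstandard}.
#'
#' @slot alignment a [ReferenceAlignment-class] of the receptors.
#' @slot ligands named character vector of ligand sequences; names are
#'   receptor ids and must match the alignment.
#' @slot nonstandard named logical vector, parallel to \code{ligands}.
#' @seealso [pairedDataset()], [covariationStatistic()]
#' @exportClass PairedDataset
setClass("PairedDataset",
  representation(alignment = "ReferenceAlignment",
                 ligands = "character",
                 nonstandard = "logical"))

setValidity("PairedDataset", function(object) {
  ids <- names(object@alignment@sequences)
  if (!identical(sort(names(object@ligands)), sort(ids)))
    return("exactly one ligand per receptor id is required")
  if (!identical(names(object@nonstandard), names(object@ligands)))
    return("nonstandard flags must parallel ligands")
  TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "ReferenceAlignment", function(object) {
  cat(sprintf(
    "ReferenceAlignment: %d sequences x %d columns (%d reference positions)\n",
    length(object@sequences), nchar(object@sequences[[1L]]),
    length(object@refToColumn)))
  cat("  reference:", object@referenceId, "\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(round(object@translation, 6), collapse = " "),
      "\n")
})

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[a$kind == "ATOM", c("chain", "resno", "icode")]))
  cat(sprintf("PDBStructure '%s': %d atoms (%d ATOM, %d HETATM), %d residues\n",
              object@id, nrow(a), sum(a$kind == "ATOM"),
              sum(a$kind == "HETATM"), nres))
})

setMethod("show", "ContactFrequencyTable", function(object) {
  t <- object@table
  cat(sprintf(
    "ContactFrequencyTable: %d positions over %d structures (high %d, mid %d, low %d)\n",
    nrow(t), if (nrow(t)) t$total[1L] else 0L,
    sum(t$bin == "high"), sum(t$bin == "mid"), sum(t$bin == "low")))
})

setMethod("show", "PairedDataset", function(object) {
  cat(sprintf("PairedDataset: %d receptor-ligand pairs (%d nonstandard ligands)\n",
              length(object@ligands), sum(object@nonstandard)))
})
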