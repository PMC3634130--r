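## Generic accessors for the S4 containers.  Slot access stays internal;
## user code goes through these.

#' @name accessors
#' @title Accessors for consite S4 containers
#' @description Small read-only accessors: sequence records, column/reference
#'   maps, atom tables and coordinates.
#' @param x an object of the documented class.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("alnSequences", function(x, ...) standardGeneric("alnSequences"))

#' @rdname accessors
#' @export
setMethod("alnSequences", "ReferenceAlignment", function(x, ...) x@sequences)

#' @rdname accessors
#' @export
setGeneric("referenceId", function(x, ...) standardGeneric("referenceId"))

#' @rdname accessors
#' @export
setMethod("referenceId", "ReferenceAlignment", function(x, ...) x@referenceId)

#' @rdname accessors
#' @export
setGeneric("columnToRef", function(x, ...) standardGeneric("columnToRef"))

#' @rdname accessors
#' @export
setMethod("columnToRef", "ReferenceAlignment", function(x, ...) x@columnToRef)

#' @rdname accessors
#' @export
setGeneric("refToColumn", function(x, ...) standardGeneric("refToColumn"))

#' @rdname accessors
#' @export
setMethod("refToColumn", "ReferenceAlignment", function(x, ...) x@refToColumn)

#' @rdname accessors
#' @export
setGeneric("structureId", function(x, ...) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setMethod("structureId", "PDBStructure", function(x, ...) x@id)

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x, ...) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setMethod("atomTable", "PDBStructure", function(x, ...) x@atoms)

#' @rdname accessors
#' @param kind optionally restrict to \code{"ATOM"} or \code{"HETATM"} rows.
#' @export
setGeneric("atomCoords", function(x, kind = NULL, ...)
  standardGeneric("atomCoords"))

#' @rdname accessors
#' @export
setMethod("atomCoords", "PDBStructure", function(x, kind = NULL, ...) {
  a <- x@atoms
  if (!is.null(kind)) a <- a[a$kind %in% kind, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
})

#' @rdname accessors
#' @export
setGeneric("ligands", function(x, ...) standardGeneric("ligands"))

#' @rdname accessors
#' @export
setMethod("ligands", "PairedDataset", function(x, ...) x@ligands)

#' @rdname accessors
#' @export
setGeneric("receptorAlignment", function(x, ...)
  standardGeneric("receptorAlignment"))

#' @rdname accessors
#' @export
setMethod("receptorAlignment", "PairedDataset", function(x, ...) x@alignment)

#' Frequency table as a data.frame
#'
#' @param x a [ContactFrequencyTable-class].
#' @param row.names,optional,... passed for S3 consistency; ignored.
#' @return data.frame with columns position, count, total, frequency, bin.
#' @method as.data.frame ContactFrequencyTable
#' @export
as.data.frame.ContactFrequencyTable <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  x@table
}

#' @exportMethod as.data.frame
setMethod("as.data.frame", "ContactFrequencyTable",
          as.data.frame.ContactFrequencyTable)

#' Rotation and translation of a rigid transform
#'
#' @param x a [RigidTransform-class].
#' @param ... unused.
#' @return \code{transformRotation}: 3x3 matrix; \code{transformTranslation}:
#'   length-3 numeric.
#' @export
setGeneric("transformRotation", function(x, ...)
  standardGeneric("transformRotation"))

#' @rdname transformRotation
#' @export
setMethod("transformRotation", "RigidTransform", function(x, ...) x@rotation)

#' @rdname transformRotation
#' @export
setGeneric("transformTranslation", function(x, ...)
  standardGeneric("transformTranslation"))

#' @rdname transformRotation
#' @export
setMethod("transformTranslation", "RigidTransform",
          function(x, ...) x@translation)
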