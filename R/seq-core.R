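## seq_core: FASTA I/O, reference numbering, scaffold checks, position
## frequency matrices and the completeness filter.

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' package's sequence contract: upper-case residues, the 20-letter alphabet
#' plus gap \code{-} and unknown \code{X}, unique record ids.
#'
#' @param path FASTA file (plain or aligned; wrapped or single-line).
#' @return named character vector of sequences, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeFasta(c(a = "CYIQ", b = "CYFQ"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "")) stop("FASTA records must carry ids")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- gsub("[[:space:]]", "", seqs)
  checkAlphabet(seqs)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or AAStringSet.
#' @param path output file.
#' @param width line-wrap width.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  seqs <- asSequenceVector(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), filepath = path, width = width)
  invisible(path)
}

#' Build a reference-numbered alignment
#'
#' Assigns increasing reference residue numbers (1, 2, ...) to the columns
#' in which the reference sequence is ungapped, and records the inverse map.
#' All position-based operations in the package ([buildPFM()],
#' [conservationProfile()], [covariationStatistic()], ...) address columns
#' through these reference numbers, mirroring the biochemical convention of
#' numbering by the human receptor sequence.
#'
#' @param sequences named character vector (or AAStringSet) of equal-length
#'   gapped sequences.
#' @param referenceId id of the reference (ungapped-numbered) sequence.
#' @return a [ReferenceAlignment-class].
#' @examples
#' aln <- referenceAlignment(c(ref = "C-YI", other = "CAY-"), "ref")
#' columnToRef(aln)   # NA at the reference gap
#' @export
referenceAlignment <- function(sequences, referenceId) {
  seqs <- asSequenceVector(sequences, "alignment sequences")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("alignment sequences must be named")
  if (length(unique(nchar(seqs))) != 1L) stop("ragged alignment")
  checkAlphabet(seqs)
  if (!(referenceId %in% names(seqs)))
    stop(sprintf("reference '%s' absent from alignment", referenceId))
  refChars <- strsplit(seqs[[referenceId]], "", fixed = TRUE)[[1L]]
  ungapped <- refChars != GAP
  columnToRef <- rep(NA_integer_, length(refChars))
  columnToRef[ungapped] <- seq_len(sum(ungapped))
  methods::new("ReferenceAlignment",
               sequences = seqs, referenceId = referenceId,
               columnToRef = columnToRef,
               refToColumn = which(ungapped))
}

#' Key human-OTR positions used throughout the analyses
#'
#' Fixed position sets (human OTR numbering): the four classical
#' binding-determinant residues, the two signalling residues, the nine
#' most-frequent ligand-contact positions seen across receptor co-crystal
#' structures, and the four positions reported to covary with the ligand.
#'
#' @return named list of integer vectors: \code{bindingDeterminants},
#'   \code{signalling}, \code{commonContacts}, \code{covarying}.
#' @export
keyPositions <- function() {
  list(
    bindingDeterminants = c(34L, 103L, 209L, 284L),
    signalling          = c(85L, 270L),
    commonContacts      = c(119L, 123L, 204L, 208L, 288L, 291L, 292L, 295L,
                            315L),
    covarying           = c(49L, 98L, 204L, 208L)
  )
}

#' Canonical nonapeptide ligand sequences
#'
#' The classical neurohypophyseal nonapeptides used as ligand fixtures:
#' oxytocin, arginine vasopressin, vasotocin, isotocin and mesotocin.  Each
#' is validated on access against the family scaffold (Cys1, Cys6, Pro7,
#' Gly9; variable positions 2--5 and 8).
#'
#' @return named character vector of nonapeptide sequences.
#' @examples
#' hammingDistance(canonicalLigands()[["oxytocin"]],
#'                 canonicalLigands()[["vasopressin"]])  # 2
#' @export
canonicalLigands <- function() {
  lig <- c(
    oxytocin    = "CYIQNCPLG",
    vasopressin = "CYFQNCPRG",
    vasotocin   = "CYIQNCPRG",
    isotocin    = "CYISNCPIG",
    mesotocin   = "CYIQNCPIG"
  )
  for (nm in names(lig)) {
    chk <- validateNonapeptide(lig[[nm]])
    if (!chk$valid)
      stop("canonical ligand ", nm, " violates the nonapeptide scaffold")
  }
  # family variability is confined to positions 2-5 and 8
  m <- seqMatrix(lig)
  varying <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  stopifnot(all(varying %in% c(2L, 3L, 4L, 5L, 8L)))
  lig
}

#' Validate a peptide against the nonapeptide scaffold
#'
#' The ligand family shares a disulfide-closed six-residue ring and a
#' three-residue tail: Cys at positions 1 and 6, Pro at 7 and Gly at 9
#' (pattern \code{CXXXXCPXG}).  \code{X} never satisfies a scaffold
#' constraint.
#'
#' @param peptide character scalar (or AAString).
#' @return list with \code{valid} (logical) and \code{violations}
#'   (character; empty when valid).  Violations are reported, never raised.
#' @export
validateNonapeptide <- function(peptide) {
  p <- asSequenceVector(peptide, "peptide")
  if (length(p) != 1L) stop("one peptide at a time")
  checkAlphabet(p, allowGap = FALSE)
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  violations <- character()
  if (length(chars) != 9L) {
    violations <- c(violations, "length")
  } else {
    if (chars[1L] != "C") violations <- c(violations, "position 1")
    if (chars[6L] != "C") violations <- c(violations, "position 6")
    if (chars[7L] != "P") violations <- c(violations, "position 7")
    if (chars[9L] != "G") violations <- c(violations, "position 9")
  }
  list(valid = length(violations) == 0L, violations = violations)
}

#' Hamming distance between equal-length sequences
#'
#' Counts differing positions.  \code{X} is treated as matching nothing, so
#' any position involving \code{X} counts as a mismatch.
#'
#' @param a,b character scalars (or AAString) of equal length.
#' @return non-negative integer.
#' @export
hammingDistance <- function(a, b) {
  a <- asSequenceVector(a, "a"); b <- asSequenceVector(b, "b")
  if (nchar(a) != nchar(b))
    stop(sprintf("unequal lengths: %d vs %d", nchar(a), nchar(b)))
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(ca != cb | ca == UNKNOWN | cb == UNKNOWN)
}

#' Position frequency matrix over reference positions
#'
#' Per requested reference position, the fraction of each residue among the
#' non-gap characters of that alignment column (the input to a sequence
#' logo).  Gaps are excluded from the denominator and reported separately;
#' an all-gap column yields an empty (all-\code{NA}) frequency column and a
#' warning.
#'
#' @param aln a [ReferenceAlignment-class].
#' @param positions reference residue numbers.
#' @return object of class \code{PositionFrequencyMatrix}: list with
#'   \code{positions}, \code{frequencies} (residues x positions matrix),
#'   \code{gapFraction} and \code{n} (non-gap counts).
#' @export
buildPFM <- function(aln, positions) {
  stopifnot(methods::is(aln, "ReferenceAlignment"))
  positions <- as.integer(positions)
  r2c <- refToColumn(aln)
  bad <- positions[positions < 1L | positions > length(r2c)]
  if (length(bad))
    stop("positions outside the reference range: ",
         paste(bad, collapse = ", "))
  m <- seqMatrix(alnSequences(aln))
  letters <- c(AA20, UNKNOWN)
  freq <- matrix(NA_real_, nrow = length(letters), ncol = length(positions),
                 dimnames = list(letters, positions))
  gapFraction <- numeric(length(positions))
  nNonGap <- integer(length(positions))
  for (k in seq_along(positions)) {
    col <- m[, r2c[positions[k]]]
    gapFraction[k] <- mean(col == GAP)
    obs <- col[col != GAP]
    nNonGap[k] <- length(obs)
    if (length(obs) == 0L) {
      warning("all-gap column at reference position ", positions[k])
      next
    }
    freq[, k] <- tabulate(factor(obs, levels = letters),
                          nbins = length(letters)) / length(obs)
  }
  structure(
    list(positions = positions, frequencies = freq,
         gapFraction = setNames(gapFraction, positions),
         n = setNames(nNonGap, positions)),
    class = "PositionFrequencyMatrix")
}

#' @export
print.PositionFrequencyMatrix <- function(x, ...) {
  cat(sprintf("PositionFrequencyMatrix: %d positions\n", length(x$positions)))
  top <- apply(x$frequencies, 2L, function(f)
    if (all(is.na(f))) "-" else rownames(x$frequencies)[which.max(f)])
  cat("  consensus:", paste(top, collapse = ""), "\n")
  invisible(x)
}

#' Partition sequences by reference coverage
#'
#' A sequence is excluded when its non-gap fraction over the
#' reference-mapped columns falls below \code{minCoverage}.  This is the
#' package's surrogate for dropping incomplete database entries before
#' similarity analysis; the default threshold of 0.8 is a package choice.
#'
#' @param aln a [ReferenceAlignment-class].
#' @param minCoverage required non-gap fraction, in (0, 1].
#' @return list with \code{kept} and \code{excluded} (ids in input order)
#'   and \code{coverage} (named numeric).
#' @export
filterIncomplete <- function(aln, minCoverage = 0.8) {
  stopifnot(methods::is(aln, "ReferenceAlignment"),
            minCoverage > 0, minCoverage <= 1)
  m <- seqMatrix(alnSequences(aln))[, refToColumn(aln), drop = FALSE]
  coverage <- rowMeans(m != GAP)
  ids <- names(alnSequences(aln))
  list(kept = ids[coverage >= minCoverage],
       excluded = ids[coverage < minCoverage],
       coverage = setNames(coverage, ids))
}
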