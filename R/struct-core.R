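## struct_core: PDB I/O (fixed-column dialect), Kabsch superposition,
## rigid transforms and Calpha geometry.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  methods::new("RigidTransform", rotation = rotation,
               translation = as.numeric(translation))
}

#' Read a structure from a PDB file
#'
#' Fixed-column parsing of ATOM/HETATM records.  Only the first MODEL of a
#' multi-model file is read; alternate locations other than blank or
#' \code{A} are dropped.  A malformed coordinate field is an error naming
#' the line.
#'
#' @param path PDB file.
#' @param id structure id; defaults to the file stem.
#' @return a [PDBStructure-class].
#' @export
readPDB <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (!length(sel)) stop("no ATOM/HETATM records in ", path)
  rec <- lines[sel]
  rec <- formatC(rec, width = 80L, flag = "-")   # pad short lines
  field <- function(from, to) trimws(substr(rec, from, to))
  num <- function(from, to, what) {
    raw <- field(from, to)
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & raw != "")
    if (length(bad))
      stop(sprintf("malformed %s field '%s' at line %d of %s",
                   what, raw[bad[1L]], sel[bad[1L]], path))
    v
  }
  x <- num(31, 38, "x coordinate"); y <- num(39, 46, "y coordinate")
  z <- num(47, 54, "z coordinate")
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1L]
    stop(sprintf("missing coordinate at line %d of %s", sel[bad], path))
  }
  occ <- num(55, 60, "occupancy"); occ[is.na(occ)] <- 1
  bfa <- num(61, 66, "B-factor");  bfa[is.na(bfa)] <- 0
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(field(7, 11))),
    kind = ifelse(substr(rec, 1, 4) == "ATOM", "ATOM", "HETATM"),
    name = field(13, 16),
    altloc = substr(rec, 17, 17),
    resname = field(18, 20),
    chain = substr(rec, 22, 22),
    resno = suppressWarnings(as.integer(field(23, 26))),
    icode = trimws(substr(rec, 27, 27)),
    x = x, y = y, z = z,
    occupancy = occ, bfactor = bfa,
    element = field(77, 78),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$resno))
    stop("malformed residue number in ", path)
  atoms <- atoms[atoms$altloc %in% c(" ", "", "A"), , drop = FALSE]
  atoms$altloc <- trimws(atoms$altloc)
  # infer missing element symbols from the atom name
  noel <- atoms$element == ""
  atoms$element[noel] <- substr(gsub("[0-9']", "", atoms$name[noel]), 1, 1)
  methods::new("PDBStructure",
               id = id %||% sub("\\.[^.]*$", "", basename(path)),
               atoms = atoms)
}

#' Write a structure to a PDB file
#'
#' Emits ATOM records (TER-terminated per chain), then HETATM records and
#' END.  Occupancy and B-factor columns are written, so annotated values
#' survive a round trip to 0.01.
#'
#' @param s a [PDBStructure-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePDB <- function(s, path) {
  stopifnot(methods::is(s, "PDBStructure"))
  a <- atomTable(s)
  fmtName <- function(name, element) {
    short <- nchar(name) < 4L & nchar(element) <= 1L
    name[short] <- paste0(" ", name[short])
    formatC(name, width = 4L, flag = "-")
  }
  fmtRec <- function(d) {
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            d$kind, d$serial %% 100000L, fmtName(d$name, d$element),
            ifelse(d$altloc == "", " ", d$altloc),
            d$resname, d$chain, d$resno,
            ifelse(d$icode == "", " ", d$icode),
            d$x, d$y, d$z, d$occupancy, d$bfactor, d$element)
  }
  out <- character()
  atm <- a[a$kind == "ATOM", , drop = FALSE]
  for (ch in unique(atm$chain)) {
    out <- c(out, fmtRec(atm[atm$chain == ch, , drop = FALSE]), "TER")
  }
  het <- a[a$kind == "HETATM", , drop = FALSE]
  if (nrow(het)) out <- c(out, fmtRec(het))
  writeLines(c(out, "END"), path)
  invisible(path)
}

# second singular value ~ 0 means the centered point set is (near) collinear
.checkNotDegenerate <- function(coords, what) {
  c0 <- sweep(coords, 2L, colMeans(coords))
  sv <- svd(c0, nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-8 * max(sv[1L], 1e-12))
    stop(what, " point set is degenerate (collinear)")
  invisible(TRUE)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{mobile} onto \code{reference} under the given point-wise
#' correspondence (SVD of the covariance matrix; the reflection branch is
#' excluded by forcing determinant +1).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3, row i of one
#'   corresponding to row i of the other.
#' @return list with \code{transform} (a [RigidTransform-class]) and
#'   \code{rmsd} (Angstrom, after transformation).
#' @examples
#' ref <- matrix(rnorm(30), 10)
#' fit <- kabschSuperpose(ref + 5, ref)
#' fit$rmsd   # ~0
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinates must be N x 3")
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have the same number of points")
  if (nrow(mobile) < 3L) stop("need at least 3 corresponding points")
  .checkNotDegenerate(mobile, "mobile")
  .checkNotDegenerate(reference, "reference")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2L, cm); R0 <- sweep(reference, 2L, cr)
  H <- crossprod(M, R0)                     # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  v <- as.numeric(cr - R %*% cm)
  tr <- rigidTransform(R, v)
  moved <- applyTransform(tr, mobile)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((moved - reference)^2))))
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a [RigidTransform-class].
#' @param coords N x 3 matrix (a length-3 vector is accepted as one point).
#' @return transformed N x 3 matrix.
#' @export
applyTransform <- function(transform, coords) {
  stopifnot(methods::is(transform, "RigidTransform"))
  one <- is.null(dim(coords))
  coords <- if (one) matrix(coords, 1L) else as.matrix(coords)
  out <- sweep(coords %*% t(transform@rotation), 2L,
               transform@translation, "+")
  if (one) out[1L, ] else out
}

# Calpha coordinates keyed "chain|resno|icode"
.caIndex <- function(s) {
  a <- atomTable(s)
  ca <- a[a$kind == "ATOM" & a$name == "CA", , drop = FALSE]
  key <- paste(ca$chain, ca$resno, ca$icode, sep = "|")
  ca <- ca[!duplicated(key), , drop = FALSE]
  structure(as.matrix(ca[, c("x", "y", "z")]),
            dimnames = list(paste(ca$chain, ca$resno, ca$icode, sep = "|"),
                            c("x", "y", "z")))
}

.pairKeys <- function(pairs, side) {
  chainCol <- paste0(side, "Chain")
  ch <- if (chainCol %in% names(pairs)) pairs[[chainCol]] else "A"
  paste(ch, pairs[[side]], "", sep = "|")
}

#' Superpose one structure onto another through a residue correspondence
#'
#' Runs [kabschSuperpose()] on the Calpha atoms of the corresponding
#' residues.  Pairs missing a Calpha on either side are dropped and
#' counted; fewer than 3 usable pairs is an error.  Superposing on Calpha
#' only is deliberate: it is insensitive to side-chain differences between
#' receptor families.
#'
#' @param mobile,reference [PDBStructure-class] objects.
#' @param pairs data.frame with columns \code{mobile} and \code{reference}
#'   (residue numbers) and optional \code{mobileChain} /
#'   \code{referenceChain} (default chain \code{"A"}).  \code{NULL} uses
#'   all (chain, residue) pairs shared by both structures.
#' @return list with \code{transform}, \code{rmsd}, \code{nUsed},
#'   \code{nDropped}.
#' @export
superposeByCorrespondence <- function(mobile, reference, pairs = NULL) {
  stopifnot(methods::is(mobile, "PDBStructure"),
            methods::is(reference, "PDBStructure"))
  caM <- .caIndex(mobile); caR <- .caIndex(reference)
  if (is.null(pairs)) {
    shared <- intersect(rownames(caM), rownames(caR))
    mKeys <- shared; rKeys <- shared
    nTotal <- length(shared)
  } else {
    mKeys <- .pairKeys(pairs, "mobile")
    rKeys <- .pairKeys(pairs, "reference")
    nTotal <- nrow(pairs)
  }
  usable <- mKeys %in% rownames(caM) & rKeys %in% rownames(caR)
  if (sum(usable) < 3L)
    stop("fewer than 3 usable Calpha correspondence pairs (",
         sum(usable), " usable of ", nTotal, ")")
  fit <- kabschSuperpose(caM[mKeys[usable], , drop = FALSE],
                         caR[rKeys[usable], , drop = FALSE])
  list(transform = fit$transform, rmsd = fit$rmsd,
       nUsed = sum(usable), nDropped = nTotal - sum(usable))
}

#' Maximum pairwise Calpha distance over selected residues
#'
#' @param s a [PDBStructure-class].
#' @param positions residue numbers, or a data.frame with \code{chain} and
#'   \code{resno}.  A plain vector matches any chain.
#' @return maximum Calpha-Calpha Euclidean distance (Angstrom); 0 for a
#'   single position.  A selected residue without a Calpha is an error
#'   naming the residue.
#' @export
maxPairwiseCaDistance <- function(s, positions) {
  stopifnot(methods::is(s, "PDBStructure"))
  a <- atomTable(s)
  ca <- a[a$kind == "ATOM" & a$name == "CA", , drop = FALSE]
  if (is.data.frame(positions)) {
    idx <- match(paste(positions$chain, positions$resno),
                 paste(ca$chain, ca$resno))
    missing <- which(is.na(idx))
    if (length(missing))
      stop("no Calpha for residue ",
           paste(positions$chain[missing], positions$resno[missing],
                 collapse = ", "))
    pts <- as.matrix(ca[idx, c("x", "y", "z")])
  } else {
    positions <- as.integer(positions)
    hit <- ca$resno %in% positions
    found <- unique(ca$resno[hit])
    missing <- setdiff(positions, found)
    if (length(missing))
      stop("no Calpha for residue ", paste(missing, collapse = ", "))
    pts <- as.matrix(ca[hit, c("x", "y", "z")])
  }
  if (nrow(pts) < 2L) return(0)
  max(dist(pts))
}
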