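# Independent oracles and small fixture builders used across the suite.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randPeptide <- function(len, alphabet = AAS) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Horn's closed-form quaternion solution to the absolute orientation
# problem -- an SVD-free route to the optimal rotation, used as the
# independent superposition oracle.
hornSuperpose <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  S <- t(M) %*% R0
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  moved <- sweep(M %*% t(R), 2, cr, "+")
  list(rotation = R, rmsd = sqrt(mean(rowSums((moved - reference)^2))))
}

randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# definitional O(N*M) distance scan: contacted residue numbers
bruteContacts <- function(structure, ligXYZ, cutoff, wholeResidue = FALSE) {
  a <- atomTable(structure)
  a <- a[a$kind == "ATOM" & a$element != "H", , drop = FALSE]
  if (!wholeResidue)
    a <- a[!(a$name %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
  hits <- integer(0)
  for (i in seq_len(nrow(a))) {
    p <- as.numeric(a[i, c("x", "y", "z")])
    for (j in seq_len(nrow(ligXYZ))) {
      if (sqrt(sum((p - as.numeric(ligXYZ[j, ]))^2)) <= cutoff) {
        hits <- c(hits, a$resno[i]); break
      }
    }
  }
  sort(unique(hits))
}

# brute-force column-to-reference map: left-to-right scan of the reference
bruteReferenceMap <- function(refSeq) {
  chars <- strsplit(refSeq, "")[[1]]
  out <- rep(NA_integer_, length(chars))
  r <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] != "-") { r <- r + 1L; out[i] <- r }
  }
  out
}

# brute-force p-distance over a pair of gapped sequences
brutePDistance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  shared <- ca != "-" & cb != "-"
  mism <- sum((ca != cb | ca == "X" | cb == "X") & shared)
  mism / sum(shared)
}

# brute-force conservation: rescaled mean over the explicit pair double loop
bruteConservation <- function(column, sim) {
  obs <- column[!(column %in% c("-", "X"))]
  if (length(obs) < 2) return(NA_real_)
  tot <- 0; np <- 0
  for (i in seq_len(length(obs) - 1)) for (j in (i + 1):length(obs)) {
    tot <- tot + sim[obs[i], obs[j]]; np <- np + 1
  }
  smin <- min(sim)
  ((tot / np) - smin) / (1 - smin)
}

# a one-residue toy structure: CB (+ optional extra side atom) around a CA
toyResidueAtoms <- function(resno, caXYZ, cbOffset = c(1.5, 0, 0),
                            resname = "LEU", chain = "A") {
  data.frame(
    serial = c(1L, 2L) + 10L * resno,
    kind = "ATOM", name = c("CA", "CB"), altloc = "",
    resname = resname, chain = chain, resno = resno, icode = "",
    x = c(caXYZ[1], caXYZ[1] + cbOffset[1]),
    y = c(caXYZ[2], caXYZ[2] + cbOffset[2]),
    z = c(caXYZ[3], caXYZ[3] + cbOffset[3]),
    occupancy = 1, bfactor = 0, element = "C",
    stringsAsFactors = FALSE)
}

toyStructure <- function(atomRows, id = "toy") {
  methods::new("PDBStructure", id = id, atoms = atomRows)
}
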