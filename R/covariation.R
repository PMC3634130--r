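## covariation: association between a receptor alignment position and a
## ligand position across receptor-ligand pairs (Cramer's V + permutation
## test), and a multiple-testing-corrected screen.

#' Build a paired receptor/ligand dataset
#'
#' @param alignment receptor [ReferenceAlignment-class].
#' @param ligands named character vector: receptor id -> ligand sequence
#'   (one per receptor).  Ligands failing [validateNonapeptide()] are kept
#'   and flagged nonstandard.
#' @return a [PairedDataset-class].
#' @export
pairedDataset <- function(alignment, ligands) {
  stopifnot(methods::is(alignment, "ReferenceAlignment"))
  ligands <- asSequenceVector(ligands, "ligands")
  ids <- names(alnSequences(alignment))
  missing <- setdiff(ids, names(ligands))
  if (length(missing))
    stop("no ligand for receptor(s): ", paste(missing, collapse = ", "))
  ligands <- ligands[ids]
  nonstandard <- !vapply(ligands, function(p) validateNonapeptide(p)$valid,
                         logical(1))
  methods::new("PairedDataset", alignment = alignment, ligands = ligands,
               nonstandard = nonstandard)
}

#' Physicochemical class of a residue
#'
#' Six classes: nonpolar-aliphatic (A, V, L, I, M), aromatic (F, Y, W),
#' polar-uncharged (S, T, N, Q), positive (K, R, H), negative (D, E) and
#' special (C, G, P).  Gaps, \code{X} and anything else map to
#' \code{"unknown"}.
#'
#' @param aa character vector of one-letter codes.
#' @return character vector of class labels.
#' @examples
#' residueClass(c("I", "L", "Y"))
#' @export
residueClass <- function(aa) {
  classes <- c(
    setNames(rep("nonpolar-aliphatic", 5), c("A", "V", "L", "I", "M")),
    setNames(rep("aromatic", 3),           c("F", "Y", "W")),
    setNames(rep("polar-uncharged", 4),    c("S", "T", "N", "Q")),
    setNames(rep("positive", 3),           c("K", "R", "H")),
    setNames(rep("negative", 2),           c("D", "E")),
    setNames(rep("special", 3),            c("C", "G", "P")))
  out <- classes[toupper(aa)]
  out[is.na(out)] <- "unknown"
  unname(out)
}

# chi-square statistic (no continuity correction) from a count table
.chisqStat <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

.cramersV <- function(rc, cc, nr, nc) {
  # rc, cc: integer category codes 1..nr / 1..nc
  tab <- matrix(tabulate(rc + nr * (cc - 1L), nbins = nr * nc), nr, nc)
  keepR <- rowSums(tab) > 0; keepC <- colSums(tab) > 0
  tab <- tab[keepR, keepC, drop = FALSE]
  k <- min(nrow(tab), ncol(tab))
  if (k < 2L) return(NA_real_)
  sqrt(.chisqStat(tab) / (sum(tab) * (k - 1)))
}

#' Covariation between a receptor position and a ligand position
#'
#' Quantifies the association between the residue observed at a receptor
#' reference position and the residue at a ligand position across all
#' receptor-ligand pairs, as Cramer's V on the category contingency table,
#' with an add-one-corrected permutation p-value obtained by shuffling the
#' ligand assignments.  In \code{"class"} mode residues are first mapped to
#' the six [residueClass()] categories (the scale on which conservative
#' receptor/ligand co-substitutions are expected); \code{"identity"} mode
#' uses the raw residues.
#'
#' Pairs where either side is a gap or \code{X} are dropped.  A position
#' constant on both sides (single category each) is reported with status
#' \code{"uninformative"} rather than statistic 0.
#'
#' @param data a [PairedDataset-class].
#' @param receptorPosition reference residue number in the receptor.
#' @param ligandPosition position 1--9 in the ligand.
#' @param mode \code{"identity"} or \code{"class"}.
#' @param nPermutations number of label permutations (>= 99).
#' @param seed RNG seed for the permutations (required for
#'   reproducibility).
#' @return list of class \code{CovariationResult}: \code{receptorPosition},
#'   \code{ligandPosition}, \code{mode}, \code{statistic},
#'   \code{permutationP}, \code{nPairs}, \code{contingency},
#'   \code{status} (\code{"ok"} or \code{"uninformative"}).
#' @export
covariationStatistic <- function(data, receptorPosition, ligandPosition,
                                 mode = c("identity", "class"),
                                 nPermutations = 9999, seed) {
  mode <- match.arg(mode)
  stopifnot(methods::is(data, "PairedDataset"), nPermutations >= 99)
  if (missing(seed)) stop("a permutation seed is required")
  aln <- receptorAlignment(data)
  r2c <- refToColumn(aln)
  if (receptorPosition < 1L || receptorPosition > length(r2c))
    stop("receptor position outside the reference range")
  recRes <- substr(alnSequences(aln), r2c[receptorPosition],
                   r2c[receptorPosition])
  lig <- ligands(data)
  if (ligandPosition < 1L || any(nchar(lig) < ligandPosition))
    stop("ligand position outside some ligand sequences")
  ligRes <- substr(lig, ligandPosition, ligandPosition)
  usable <- !(recRes %in% c(GAP, UNKNOWN)) & !(ligRes %in% c(GAP, UNKNOWN))
  if (sum(usable) < 5L)
    stop("fewer than 5 usable pairs (", sum(usable), ")")
  r <- recRes[usable]; l <- ligRes[usable]
  if (mode == "class") { r <- residueClass(r); l <- residueClass(l) }
  contingency <- table(receptor = r, ligand = l)
  base <- list(receptorPosition = as.integer(receptorPosition),
               ligandPosition = as.integer(ligandPosition), mode = mode,
               nPairs = sum(usable), contingency = contingency)
  if (length(unique(r)) < 2L || length(unique(l)) < 2L) {
    return(structure(c(base, list(statistic = NA_real_,
                                  permutationP = NA_real_,
                                  status = "uninformative")),
                     class = "CovariationResult"))
  }
  rf <- factor(r); cf <- factor(l)
  rc <- as.integer(rf); cc <- as.integer(cf)
  nr <- nlevels(rf); nc <- nlevels(cf)
  obs <- .cramersV(rc, cc, nr, nc)
  nGE <- withSeed(seed, {
    sum(vapply(seq_len(nPermutations), function(k) {
      .cramersV(rc, cc[sample.int(length(cc))], nr, nc)
    }, numeric(1)) >= obs - 1e-12)
  })
  structure(c(base, list(statistic = obs,
                         permutationP = (1 + nGE) / (nPermutations + 1),
                         status = "ok")),
            class = "CovariationResult")
}

#' @export
print.CovariationResult <- function(x, ...) {
  cat(sprintf("CovariationResult: receptor %d vs ligand %d (%s mode)\n",
              x$receptorPosition, x$ligandPosition, x$mode))
  if (x$status == "uninformative") {
    cat("  uninformative (constant on at least one side)\n")
  } else {
    cat(sprintf("  Cramer's V = %.3f, permutation p = %.4g, n = %d\n",
                x$statistic, x$permutationP, x$nPairs))
  }
  invisible(x)
}

#' Screen all receptor x ligand position pairs for covariation
#'
#' Runs [covariationStatistic()] for every combination and applies
#' Benjamini-Hochberg adjustment across the informative tests.
#'
#' @param data a [PairedDataset-class].
#' @param receptorPositions reference residue numbers to test.
#' @param ligandPositions ligand positions to test (default: the variable
#'   scaffold positions 2--5 and 8).
#' @param mode,nPermutations,seed see [covariationStatistic()]; per-test
#'   seeds are derived from \code{seed}.
#' @return data.frame with one row per tested pair: positions, statistic,
#'   p, q (BH-adjusted), nPairs, status; sorted by q then p.
#' @export
screenAll <- function(data, receptorPositions,
                      ligandPositions = c(2L, 3L, 4L, 5L, 8L),
                      mode = c("identity", "class"),
                      nPermutations = 9999, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a permutation seed is required")
  grid <- expand.grid(receptor = as.integer(receptorPositions),
                      ligand = as.integer(ligandPositions))
  if (nrow(grid) == 0L)
    return(data.frame(receptorPosition = integer(), ligandPosition = integer(),
                      statistic = numeric(), p = numeric(), q = numeric(),
                      nPairs = integer(), status = character()))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    res <- covariationStatistic(
      data, grid$receptor[k], grid$ligand[k], mode = mode,
      nPermutations = nPermutations,
      seed = (as.integer(seed) + 7919L * k) %% .Machine$integer.max)
    data.frame(receptorPosition = res$receptorPosition,
               ligandPosition = res$ligandPosition,
               statistic = res$statistic %||% NA_real_,
               p = res$permutationP, nPairs = res$nPairs,
               status = res$status)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- out$status == "ok"
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  # among permutation-p ties, stronger associations first
  out <- out[order(out$q, out$p, -out$statistic,
                   out$receptorPosition, out$ligandPosition), ]
  rownames(out) <- NULL
  out[, c("receptorPosition", "ligandPosition", "statistic", "p", "q",
          "nPairs", "status")]
}
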