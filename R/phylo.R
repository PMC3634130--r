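## phylo: distances, neighbor joining, Newick I/O, conservation profile,
## clade purity report.

.simCache <- new.env(parent = emptyenv())

#' Normalized residue similarity matrix
#'
#' A standard log-odds substitution matrix (BLOSUM62, shipped with
#' Biostrings) normalized per residue pair as
#' \code{score(a,b) / sqrt(score(a,a) * score(b,b))}, so every identity
#' scores exactly 1 and the most dissimilar residue pairs score negatively.
#' This is the gradient used by [conservationProfile()] (identical column
#' scores 1; "opposite-type" columns approach 0 after rescaling) and the
#' proposal kernel of [simulateFamily()].
#'
#' @return 20x20 numeric matrix over the standard residues.
#' @export
residueSimilarity <- function() {
  if (is.null(.simCache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b <- e$BLOSUM62[AA20, AA20]
    d <- diag(b)
    .simCache$mat <- b / sqrt(outer(d, d))
  }
  .simCache$mat
}

#' Pairwise distances between aligned sequences
#'
#' Two models: \code{"p"} (p-distance: mismatches over shared non-gap
#' columns; \code{X} counts as a mismatch) and \code{"similarity"}
#' (1 minus the mean normalized substitution score over shared non-gap,
#' non-\code{X} columns; identical sequences score distance 0).
#'
#' @param aln a [ReferenceAlignment-class] (or named character vector of
#'   equal-length sequences).
#' @param model distance model.
#' @param similarityMatrix matrix used by the similarity model.
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
pairwiseDistances <- function(aln, model = c("p", "similarity"),
                              similarityMatrix = residueSimilarity()) {
  model <- match.arg(model)
  seqs <- if (methods::is(aln, "ReferenceAlignment")) alnSequences(aln)
          else asSequenceVector(aln)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- seqMatrix(seqs)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    shared <- a != GAP & b != GAP
    if (model == "similarity") shared <- shared & a != UNKNOWN & b != UNKNOWN
    if (!any(shared))
      stop(sprintf("no shared non-gap columns between '%s' and '%s'",
                   rownames(m)[i], rownames(m)[j]))
    d[i, j] <- d[j, i] <-
      if (model == "p") {
        aa <- a[shared]; bb <- b[shared]
        mean(aa != bb | aa == UNKNOWN | bb == UNKNOWN)
      } else {
        1 - mean(similarityMatrix[cbind(a[shared], b[shared])])
      }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining on the Q-criterion, exact on additive distance
#' matrices.  Deterministic: when several pairs share the minimal Q value,
#' the pair with the lexicographically smallest current index pair (i, j)
#' is joined.  Negative branch lengths are clamped to zero.
#'
#' @param d symmetric distance matrix (zero diagonal, non-negative, labelled
#'   rows/columns), at least 3 taxa.
#' @return unrooted \code{ape::phylo} tree over the matrix labels.
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' neighborJoining(d)
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("negative distances")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  labels <- rownames(d)

  # nodes: tips get newick leaf tokens; joins build nested tokens
  token <- sprintf("t%d", seq_len(n))       # placeholder-safe labels
  D <- d
  fmt <- function(x) sprintf("%.17g", x)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    # lexicographically smallest (i, j), i < j, among minimal Q
    qmin <- min(Q)
    hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    bi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    newTok <- sprintf("(%s:%s,%s:%s)", token[i], fmt(bi), token[j], fmt(bj))
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    token <- c(token[keep], newTok)
    D <- D2
  }
  # closed-form three-point finish (trifurcating basal node)
  x <- D[1, 2]; y <- D[1, 3]; z <- D[2, 3]
  b1 <- max((x + y - z) / 2, 0)
  b2 <- max((x + z - y) / 2, 0)
  b3 <- max((y + z - x) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", token[1L], fmt(b1),
                 token[2L], fmt(b2), token[3L], fmt(b3))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

# quote a Newick label when it contains structural characters
.quoteNewickLabel <- function(x) {
  needs <- grepl("[][(),:;'[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with enough digits for a 1e-9 round trip;
#' labels containing Newick metacharacters are single-quoted.
#'
#' @param tree an \code{ape::phylo} object.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  len <- tree$edge.length
  lab <- .quoteNewickLabel(tree$tip.label)
  rec <- function(node, edgeIdx) {
    body <- if (node <= ntip) {
      lab[node]
    } else {
      kids <- children[[as.character(node)]]
      paste0("(", paste(vapply(kids, function(e)
        rec(tree$edge[e, 2L], e), ""), collapse = ","), ")")
    }
    if (is.na(edgeIdx) || is.null(len)) body
    else sprintf("%s:%.17g", body, len[edgeIdx])
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  writeLines(paste0(rec(root, NA), ";"), path)
  invisible(path)
}

#' Read a tree from a Newick file
#'
#' @param path Newick file; a parse failure is an error (unbalanced
#'   parentheses are reported with the character offset).
#' @return an \code{ape::phylo} object.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # balance scan (outside quoted labels) for a located diagnostic
  depth <- 0L; inq <- FALSE
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "'") inq <- !inq
    else if (!inq && ch == "(") depth <- depth + 1L
    else if (!inq && ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unbalanced ')' at character ", k)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of input")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || is.null(tree$tip.label))
    stop("malformed Newick in ", path)
  # undo label quoting
  q <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[q] <- gsub("''", "'",
                            sub("^'(.*)'$", "\\1", tree$tip.label[q]))
  tree
}

#' Per-position conservation profile of an alignment
#'
#' For every reference-mapped column, the mean pairwise normalized
#' substitution score over all non-gap sequence pairs, rescaled to [0, 1]:
#' an invariant column scores exactly 1 and a column of maximally dissimilar
#' residue types approaches 0.  This is the per-residue colour gradient for
#' structure annotation (dark blue = identical down to red = opposite
#' residue type).  Pairs involving a gap or \code{X} are excluded; columns
#' with fewer than 2 scorable characters carry no score.
#'
#' @param aln a [ReferenceAlignment-class].
#' @param similarityMatrix normalized similarity matrix, see
#'   [residueSimilarity()].
#' @return data.frame with columns \code{position}, \code{column}, \code{n},
#'   \code{score}, \code{majority}.
#' @export
conservationProfile <- function(aln, similarityMatrix = residueSimilarity()) {
  stopifnot(methods::is(aln, "ReferenceAlignment"))
  m <- seqMatrix(alnSequences(aln))
  r2c <- refToColumn(aln)
  smin <- min(similarityMatrix)
  out <- data.frame(position = seq_along(r2c), column = r2c,
                    n = NA_integer_, score = NA_real_,
                    majority = NA_character_)
  for (k in seq_along(r2c)) {
    col <- m[, r2c[k]]
    obs <- col[col != GAP & col != UNKNOWN]
    out$n[k] <- length(obs)
    if (length(obs) < 2L) next
    counts <- table(obs)
    res <- names(counts); cnt <- as.numeric(counts)
    # mean over unordered pairs via counts (equivalent to the double loop)
    tot <- sum(cnt)
    S <- similarityMatrix[res, res, drop = FALSE]
    pairSum <- (sum(outer(cnt, cnt) * S) - sum(cnt * diag(S))) / 2
    meanScore <- pairSum / (tot * (tot - 1) / 2)
    out$score[k] <- (meanScore - smin) / (1 - smin)
    out$majority[k] <- res[order(-cnt, res)][1L]
  }
  out
}

#' Monophyly report for labelled leaf groups
#'
#' For each group of leaves, reports whether the group is monophyletic in
#' the unrooted tree (i.e. separated from the rest by a single edge) and
#' the size of the smallest clade containing it.
#'
#' @param tree an \code{ape::phylo}.
#' @param groupMap named character vector: leaf label -> group label.
#'   Every name must be a tree leaf; leaves without an entry are ignored as
#'   background.
#' @return data.frame with \code{group}, \code{n}, \code{monophyletic},
#'   \code{cladeSize}.
#' @export
clusterReport <- function(tree, groupMap) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  unknown <- setdiff(names(groupMap), tips)
  if (length(unknown))
    stop("group map names absent from tree: ",
         paste(unknown, collapse = ", "))
  groups <- split(names(groupMap), unname(groupMap))
  res <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    if (length(members) == 1L)
      return(data.frame(group = g, n = 1L, monophyletic = TRUE,
                        cladeSize = 1L))
    if (length(members) == length(tips))
      return(data.frame(group = g, n = length(members), monophyletic = TRUE,
                        cladeSize = length(tips)))
    out <- setdiff(tips, members)[1L]
    rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
    mrca <- ape::getMRCA(rooted, members)
    clade <- ape::extract.clade(rooted, mrca)$tip.label
    data.frame(group = g, n = length(members),
               monophyletic = setequal(clade, members),
               cladeSize = length(clade))
  })
  do.call(rbind, res)
}
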