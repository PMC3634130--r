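# shared internal helpers: alphabet constants, seeded evaluation, checks

# the 20 standard residues, alphabetical one-letter order
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")
AA1 <- setNames(names(AA3), unname(AA3))

GAP <- "-"
UNKNOWN <- "X"

# evaluate `code` with the RNG seeded, restoring the caller's RNG state
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# coerce AAStringSet / named character to a validated named character vector
asSequenceVector <- function(x, what = "sequences") {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop(what, " must be a character vector or AAStringSet")
  if (length(x) == 0L) stop(what, " is empty")
  toupper(x)
}

checkAlphabet <- function(seqs, allowGap = TRUE) {
  ok <- c(AA20, UNKNOWN, if (allowGap) GAP)
  chars <- unique(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE))
  bad <- setdiff(chars, ok)
  if (length(bad))
    stop("invalid residue code(s): ", paste(sQuote(bad), collapse = ", "),
         " (ambiguity codes other than X are not accepted)")
  invisible(TRUE)
}

# character matrix view of equal-length sequences (rows = sequences)
seqMatrix <- function(seqs) {
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) stop("sequences have unequal lengths")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
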