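# DNA generalization lattice over the 16-symbol extended alphabet
# (IUPAC ambiguity codes plus the alignment gap).

#' @name lattice
#' @title The DNA generalization lattice
#'
#' @description
#' The obfuscation algebra works on a four-level lattice over the extended
#' DNA alphabet: the four bases A, C, G, T at level 1; the six two-base
#' IUPAC ambiguity codes R, W, M, K, S, Y at level 2; the four three-base
#' codes D, V, H, B and the alignment gap \code{"-"} at level 3; and N,
#' which stands for any base or a gap, at level 4. Each symbol denotes a
#' set of possible bases (the gap denotes the singleton \{-\}); a symbol is
#' an ancestor of another when its base set is a superset. Generalizing two
#' aligned symbols replaces them with their lowest common ancestor, and the
#' information lost by doing so is scored by the level-based distance
#' \code{2*lev(g(a,b)) - lev(a) - lev(b)}.
#'
#' Lowercase input is accepted and upcased. The RNA base U is rejected:
#' this is a DNA-only tool and silently converting U to T would mask data
#' problems.
NULL

## Symbol order is fixed; all internal tables are indexed by it.
LATTICE_ALPHABET <- c("A", "C", "G", "T",
                      "R", "W", "M", "K", "S", "Y",
                      "D", "V", "H", "B", "-",
                      "N")

.BASE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), W = c("A", "T"), M = c("A", "C"),
  K = c("G", "T"), S = c("C", "G"), Y = c("C", "T"),
  D = c("A", "G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), B = c("C", "G", "T"),
  `-` = "-",
  N = c("A", "C", "G", "T", "-")
)

.LEVELS <- c(A = 1L, C = 1L, G = 1L, T = 1L,
             R = 2L, W = 2L, M = 2L, K = 2L, S = 2L, Y = 2L,
             D = 3L, V = 3L, H = 3L, B = 3L, `-` = 3L,
             N = 4L)

.LEV <- unname(.LEVELS[LATTICE_ALPHABET])

## Lowest common ancestor table: for every symbol pair the unique
## lowest-level symbol whose base set contains the union of the two base
## sets. Built once from the base-set definition; uniqueness is asserted.
.buildGeneralizeTable <- function() {
  n <- length(LATTICE_ALPHABET)
  tab <- matrix(NA_integer_, n, n,
                dimnames = list(LATTICE_ALPHABET, LATTICE_ALPHABET))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      un <- union(.BASE_SETS[[i]], .BASE_SETS[[j]])
      cand <- which(vapply(.BASE_SETS,
                           function(b) all(un %in% b), logical(1)))
      best <- cand[.LEV[cand] == min(.LEV[cand])]
      stopifnot(length(best) == 1L)
      tab[i, j] <- best
    }
  }
  tab
}

.GEN <- .buildGeneralizeTable()
.DIST <- 2L * matrix(.LEV[.GEN], 16L, 16L,
                     dimnames = dimnames(.GEN)) - outer(.LEV, .LEV, `+`)

## byte -> symbol index lookup (1..16), NA for invalid bytes, -1 for U/u
.CODE_LOOKUP <- local({
  lk <- rep(NA_integer_, 256L)
  for (i in seq_along(LATTICE_ALPHABET)) {
    ch <- LATTICE_ALPHABET[i]
    lk[utf8ToInt(ch) + 1L] <- i
    lo <- tolower(ch)
    if (lo != ch) lk[utf8ToInt(lo) + 1L] <- i
  }
  lk[utf8ToInt("U") + 1L] <- -1L
  lk[utf8ToInt("u") + 1L] <- -1L
  lk
})

.ALPH_INT <- vapply(LATTICE_ALPHABET, utf8ToInt, integer(1))

## Encode a single sequence string into 1-based symbol indices.
.encodeSeq <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop(what, " must be a single character string")
  ints <- utf8ToInt(s)
  idx <- .CODE_LOOKUP[ifelse(ints < 256L, ints + 1L, NA_integer_)]
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop(sprintf("invalid symbol '%s' at position %d of %s",
                 substr(s, p, p), p, what))
  }
  bad <- idx == -1L
  if (any(bad)) {
    p <- which(bad)[1L]
    stop(sprintf(
      "RNA base 'U' at position %d of %s: only DNA symbols are supported",
      p, what))
  }
  idx
}

.decodeSeq <- function(idx) {
  if (length(idx) == 0L) return("")
  intToUtf8(.ALPH_INT[idx])
}

## Encode a vector of single-character symbol codes.
.encodeSymbols <- function(codes, arg = "code") {
  if (!is.character(codes))
    stop(arg, " must be a character vector of single symbols")
  if (any(nchar(codes) != 1L))
    stop(arg, " must contain single characters, got: ",
         paste(unique(codes[nchar(codes) != 1L]), collapse = ", "))
  idx <- integer(length(codes))
  for (i in seq_along(codes))
    idx[i] <- .encodeSeq(codes[i], what = sprintf("%s[%d]", arg, i))
  idx
}

#' Lattice symbol table
#'
#' @return A data.frame with one row per extended-alphabet symbol: its
#'   \code{code}, its lattice \code{level} (1-4) and the bases it denotes
#'   (comma-separated; the gap denotes itself).
#' @examples
#' latticeSymbols()
#' @export
latticeSymbols <- function() {
  data.frame(
    code = LATTICE_ALPHABET,
    level = .LEV,
    bases = vapply(.BASE_SETS, paste, character(1), collapse = ","),
    row.names = NULL
  )
}

#' Lattice level of a symbol
#'
#' @param code character vector of single symbols from the extended
#'   alphabet (A, C, G, T, R, W, M, K, S, Y, D, V, H, B, N, or \code{"-"};
#'   lowercase accepted).
#' @return Integer vector of levels (1-4).
#' @examples
#' latticeLevel(c("A", "Y", "-", "N"))  # 1 2 3 4
#' @export
latticeLevel <- function(code) {
  .LEV[.encodeSymbols(code)]
}

#' Base-set interpretation of a symbol
#'
#' @param code a single symbol code.
#' @return Character vector of the bases (and/or gap) the symbol denotes.
#' @examples
#' latticeBases("D")  # A G T
#' @export
latticeBases <- function(code) {
  .BASE_SETS[[.encodeSymbols(code, arg = "code")[1L]]]
}

#' Generalize (obfuscate) two aligned symbols
#'
#' Returns the lowest common ancestor of the two symbols in the
#' generalization lattice: the unique lowest-level symbol whose base set
#' contains the union of both base sets. The operation is commutative and
#' idempotent; generalizing a base against the gap yields N.
#'
#' @param a,b character vectors of single symbols (recycled elementwise).
#' @return Character vector of generalized symbols.
#' @examples
#' generalizeSymbols("C", "A")   # "M"
#' generalizeSymbols("T", "-")   # "N"
#' generalizeSymbols("R", "Y")   # "N"
#' @export
generalizeSymbols <- function(a, b) {
  ia <- .encodeSymbols(a, "a")
  ib <- .encodeSymbols(b, "b")
  n <- max(length(ia), length(ib))
  ia <- rep_len(ia, n)
  ib <- rep_len(ib, n)
  LATTICE_ALPHABET[.GEN[cbind(ia, ib)]]
}

#' Per-nucleotide obfuscation distance
#'
#' The information loss incurred by generalizing two aligned symbols:
#' \code{2*lev(g(a,b)) - lev(a) - lev(b)}, where \code{g} is the lowest
#' common ancestor and \code{lev} the lattice level. Symmetric,
#' non-negative, and zero exactly when the symbols are equal.
#'
#' @inheritParams generalizeSymbols
#' @return Integer vector of distances.
#' @examples
#' symbolDistance("C", "A")  # 2
#' symbolDistance("T", "-")  # 4
#' symbolDistance("A", "R")  # 1
#' @export
symbolDistance <- function(a, b) {
  ia <- .encodeSymbols(a, "a")
  ib <- .encodeSymbols(b, "b")
  n <- max(length(ia), length(ib))
  ia <- rep_len(ia, n)
  ib <- rep_len(ib, n)
  unname(.DIST[cbind(ia, ib)])
}

#' Lattice distance between two aligned sequences
#'
#' Sums the per-nucleotide obfuscation distance over all columns of two
#' already-aligned (equal-length, possibly gapped) sequences.
#'
#' @param x,y single character strings of equal length over the extended
#'   alphabet.
#' @return A single non-negative integer.
#' @examples
#' sequenceDistance("CCTGTAAA", "CA-GTRAA")  # 7
#' @export
sequenceDistance <- function(x, y) {
  ix <- .encodeSeq(.asSingleSeq(x), "x")
  iy <- .encodeSeq(.asSingleSeq(y), "y")
  if (length(ix) != length(iy))
    stop(sprintf(
      "aligned sequences must have equal length, got %d and %d",
      length(ix), length(iy)))
  sum(.DIST[cbind(ix, iy)])
}

#' Obfuscate a pair of aligned sequences
#'
#' Column-wise generalization of two aligned sequences: each column is
#' replaced by the lowest common ancestor of its two symbols. The total
#' cost equals \code{\link{sequenceDistance}} of the pair, and an event is
#' recorded for every column whose cost is positive (i.e. whose symbols
#' differ).
#'
#' @inheritParams sequenceDistance
#' @return A list with elements \code{generalized} (the obfuscated
#'   sequence), \code{cost} (total lattice distance, integer) and
#'   \code{events}, a data.frame with one row per changed column:
#'   \code{column} (1-based alignment column), \code{left}, \code{right},
#'   \code{generalized}, \code{cost}.
#' @examples
#' ob <- obfuscatePair("CCTGTAAA", "CA-GTRAA")
#' ob$generalized  # "CMNGTRAA"
#' ob$cost         # 7
#' @export
obfuscatePair <- function(x, y) {
  ix <- .encodeSeq(.asSingleSeq(x), "x")
  iy <- .encodeSeq(.asSingleSeq(y), "y")
  if (length(ix) != length(iy))
    stop(sprintf(
      "aligned sequences must have equal length, got %d and %d",
      length(ix), length(iy)))
  ig <- .GEN[cbind(ix, iy)]
  costs <- .DIST[cbind(ix, iy)]
  chg <- which(costs > 0L)
  list(
    generalized = .decodeSeq(ig),
    cost = as.integer(sum(costs)),
    events = data.frame(
      column = chg,
      left = LATTICE_ALPHABET[ix[chg]],
      right = LATTICE_ALPHABET[iy[chg]],
      generalized = LATTICE_ALPHABET[ig[chg]],
      cost = costs[chg],
      row.names = NULL
    )
  )
}

#' Lattice cost matrix
#'
#' @return The full 16 x 16 integer matrix of per-nucleotide obfuscation
#'   distances, with symbol codes as dimnames. Row/column order matches
#'   \code{\link{latticeSymbols}}.
#' @export
latticeCostMatrix <- function() .DIST

## Coerce a single sequence (character(1), DNAString, or length-1
## DNAStringSet) to a plain string.
.asSingleSeq <- function(x) {
  if (methods::is(x, "XString") ||
      (methods::is(x, "XStringSet") && length(x) == 1L))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single sequence (character string or DNAString)")
  unname(x)
}
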