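# Independent oracles: every table here is re-declared from the symbol
# definitions and every algorithm is a brute-force or alternative-route
# implementation, so package internals are never used to check themselves.

ORACLE_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), W = c("A", "T"), M = c("A", "C"),
  K = c("G", "T"), S = c("C", "G"), Y = c("C", "T"),
  D = c("A", "G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), B = c("C", "G", "T"),
  `-` = "-",
  N = c("A", "C", "G", "T", "-"))

ORACLE_LEVEL <- c(A = 1, C = 1, G = 1, T = 1,
                  R = 2, W = 2, M = 2, K = 2, S = 2, Y = 2,
                  D = 3, V = 3, H = 3, B = 3, `-` = 3,
                  N = 4)

ORACLE_SYMBOLS <- names(ORACLE_BASES)

## brute-force search for the minimal superset symbol
bruteGeneralize <- function(a, b) {
  un <- union(ORACLE_BASES[[a]], ORACLE_BASES[[b]])
  ok <- vapply(ORACLE_BASES, function(s) all(un %in% s), logical(1))
  cand <- ORACLE_SYMBOLS[ok]
  cand[which.min(ORACLE_LEVEL[cand])]
}

oracleNtDist <- function(a, b) {
  g <- bruteGeneralize(a, b)
  2 * ORACLE_LEVEL[[g]] - ORACLE_LEVEL[[a]] - ORACLE_LEVEL[[b]]
}

ORACLE_DIST <- outer(ORACLE_SYMBOLS, ORACLE_SYMBOLS,
                     Vectorize(oracleNtDist))
dimnames(ORACLE_DIST) <- list(ORACLE_SYMBOLS, ORACLE_SYMBOLS)

oracleSeqDist <- function(x, y) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  stopifnot(length(xs) == length(ys))
  sum(ORACLE_DIST[cbind(xs, ys)])
}

## exhaustive enumeration of every global alignment (no memoization;
## exponential, tiny inputs only)
enumAlignCost <- function(x, y) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  nx <- length(xs)
  ny <- length(ys)
  rec <- function(i, j) {
    if (i > nx && j > ny) return(0)
    best <- Inf
    if (i <= nx && j <= ny)
      best <- min(best, ORACLE_DIST[xs[i], ys[j]] + rec(i + 1, j + 1))
    if (i <= nx)
      best <- min(best, ORACLE_DIST[xs[i], "-"] + rec(i + 1, j))
    if (j <= ny)
      best <- min(best, ORACLE_DIST[ys[j], "-"] + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

## independent pure-R dynamic program for the minimum alignment cost
rDpAlignCost <- function(x, y) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  n <- length(xs)
  m <- length(ys)
  gap <- ORACLE_DIST[, "-"]
  D <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) D[i + 1, 1] <- D[i, 1] + gap[xs[i]]
  for (j in seq_len(m)) D[1, j + 1] <- D[1, j] + gap[ys[j]]
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1, j + 1] <- min(D[i, j] + ORACLE_DIST[xs[i], ys[j]],
                             D[i, j + 1] + gap[xs[i]],
                             D[i + 1, j] + gap[ys[j]])
  D[n + 1, m + 1]
}

## minimum total weight over all perfect matchings, by recursion
enumPerfectMatching <- function(d) {
  rec <- function(rem) {
    if (length(rem) == 0) return(0)
    a <- rem[1]
    best <- Inf
    for (b in rem[-1]) {
      v <- d[a, b] + rec(setdiff(rem, c(a, b)))
      if (v < best) best <- v
    }
    best
  }
  rec(seq_len(nrow(d)))
}

## maximum total weight over all perfect matchings (worst pairing)
enumWorstMatching <- function(d) {
  rec <- function(rem) {
    if (length(rem) == 0) return(0)
    a <- rem[1]
    best <- -Inf
    for (b in rem[-1]) {
      v <- d[a, b] + rec(setdiff(rem, c(a, b)))
      if (v > best) best <- v
    }
    best
  }
  rec(seq_len(nrow(d)))
}

## small sequence generators
randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## derive a mutated copy: nsub random substitutions
mutateSeq <- function(s, nsub) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), min(nsub, length(v)))
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

## a small family of mutated copies of one reference
mutantFamily <- function(n, len, nsub = 2) {
  ref <- randSeq(len)
  seqs <- vapply(seq_len(n), function(i) mutateSeq(ref, nsub),
                 character(1))
  names(seqs) <- sprintf("m%02d", seq_len(n))
  seqs
}
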