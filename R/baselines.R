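# Baseline clustering strategies sharing the same obfuscation backend:
# exact minimum-weight perfect matching, greedy closest-pair extraction,
# and random pairing.

#' All pairwise alignment distances
#'
#' Computes the full symmetric matrix of pairwise global alignment costs
#' (lattice distances) for a dataset.
#'
#' @param dataset named character vector or \code{DNAStringSet} with at
#'   least two sequences.
#' @param band see \code{\link{alignPair}}.
#' @return A symmetric integer matrix with zero diagonal and sequence
#'   identifiers as dimnames.
#' @export
pairwiseDistances <- function(dataset, band = 0L) {
  seqs <- .asSeqSet(dataset)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (anyDuplicated(names(seqs)))
    stop("sequence identifiers must be unique")
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- as.integer(
        .alignRaw(seqs[[i]], seqs[[j]], band)$cost)
  d
}

## Attach a leftover sequence to the matched pair whose closer member is
## nearest (ties: earlier pair). Returns the pair index.
.nearestPair <- function(d, leftover, pairs) {
  score <- vapply(pairs, function(p) min(d[leftover, p]), numeric(1))
  which.min(score)
}

## Build a ClusteringResult from a list of member-index vectors.
.obfuscateAll <- function(seqs, memberSets, method, seed, band) {
  clusters <- lapply(seq_along(memberSets), function(i)
    obfuscateCluster(seqs[memberSets[[i]]], band = band, clusterId = i))
  .newClusteringResult(clusters, method, 2L, seed, names(seqs))
}

#' Minimum-weight perfect-matching clustering
#'
#' Pairs all sequences so that the total pairwise alignment distance is
#' minimal, using an exact general-graph minimum-weight perfect matching
#' on the full distance matrix. For odd N the leftover sequence (chosen
#' so the matching over the rest is optimal) joins the matched pair
#' whose closer member is nearest, forming one triple obfuscated by the
#' chained rule. Deterministic; no seed is involved.
#'
#' @inheritParams pairwiseDistances
#' @return A \code{\linkS4class{ClusteringResult}} with method tag
#'   \code{"mwm"}.
#' @export
mwmCluster <- function(dataset, band = 0L) {
  seqs <- .asSeqSet(dataset)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  d <- pairwiseDistances(seqs, band)
  n <- length(seqs)
  odd <- n %% 2L == 1L
  dm <- d
  if (odd) {
    ## dummy node with zero-cost edges: its partner is the leftover and
    ## the matching over the remaining n-1 nodes is globally optimal
    dm <- rbind(cbind(d, 0L), 0L)
  }
  m <- .mwpmCpp(dm)
  leftover <- if (odd) m[n + 1L] else 0L
  firsts <- which(seq_len(n) < m[seq_len(n)] & seq_len(n) != leftover)
  firsts <- firsts[m[firsts] <= n]
  pairs <- lapply(firsts, function(i) c(i, m[i]))
  if (odd) {
    at <- .nearestPair(d, leftover, pairs)
    pairs[[at]] <- c(pairs[[at]], leftover)
  }
  .obfuscateAll(seqs, pairs, "mwm", NA_integer_, band)
}

#' Greedy closest-pair clustering
#'
#' Repeatedly extracts the globally closest remaining pair from the
#' distance matrix (ties broken by smaller row index, then smaller
#' column index). For odd N the final unpaired sequence joins the
#' matched pair whose closer member is nearest. Deterministic.
#'
#' @inheritParams pairwiseDistances
#' @return A \code{\linkS4class{ClusteringResult}} with method tag
#'   \code{"greedy"}.
#' @export
greedyCluster <- function(dataset, band = 0L) {
  seqs <- .asSeqSet(dataset)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  d <- pairwiseDistances(seqs, band)
  n <- length(seqs)
  remaining <- seq_len(n)
  pairs <- list()
  while (length(remaining) >= 2L) {
    sub <- d[remaining, remaining, drop = FALSE]
    best <- NULL
    bestVal <- Inf
    for (i in seq_len(length(remaining) - 1L))
      for (j in (i + 1L):length(remaining))
        if (sub[i, j] < bestVal) {
          bestVal <- sub[i, j]
          best <- c(i, j)
        }
    pair <- remaining[best]
    pairs[[length(pairs) + 1L]] <- pair
    remaining <- setdiff(remaining, pair)
  }
  if (length(remaining) == 1L) {
    at <- .nearestPair(d, remaining, pairs)
    pairs[[at]] <- c(pairs[[at]], remaining)
  }
  .obfuscateAll(seqs, pairs, "greedy", NA_integer_, band)
}

#' Random pairing baseline
#'
#' Shuffles the dataset with a seeded permutation and pairs consecutive
#' sequences; for odd N the last sequence joins the last pair. This is
#' the no-information baseline against which similarity-aware clustering
#' is compared.
#'
#' @inheritParams pairwiseDistances
#' @param seed integer seed for the permutation.
#' @return A \code{\linkS4class{ClusteringResult}} with method tag
#'   \code{"random"}.
#' @export
randomCluster <- function(dataset, seed = 1L, band = 0L) {
  seqs <- .asSeqSet(dataset)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (anyDuplicated(names(seqs)))
    stop("sequence identifiers must be unique")
  .withSeed(seed, function() {
    perm <- sample.int(n)
    nPairs <- n %/% 2L
    pairs <- lapply(seq_len(nPairs), function(i)
      perm[c(2L * i - 1L, 2L * i)])
    if (n %% 2L == 1L)
      pairs[[nPairs]] <- c(pairs[[nPairs]], perm[n])
    .obfuscateAll(seqs, pairs, "random", seed, band)
  })
}
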