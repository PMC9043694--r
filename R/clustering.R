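# Iterative similarity-search clustering into k-anonymous groups, the
# chained cluster obfuscation, and the anonymity degree.

## Restore the caller's RNG state after a seeded computation.
.withSeed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

## Insert "-" columns at the given (new-coordinate) positions.
.insertGapCols <- function(s, ins) {
  if (length(ins) == 0L) return(s)
  old <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(length(old) + length(ins))
  out[ins] <- "-"
  out[-ins] <- old
  paste(out, collapse = "")
}

#' Obfuscate one cluster of sequences
#'
#' Folds the members of a cluster, in the given (ranked) order, into a
#' single generalized sequence: the first two members are globally
#' aligned and obfuscated column-wise; each further member is then
#' aligned against the current generalized sequence and obfuscated onto
#' it (the chained second obfuscation used for leftover clusters). When
#' a later alignment inserts new gap columns into the generalized
#' sequence, the same columns are inserted into the stored aligned forms
#' of the earlier members and into recorded event positions, so all
#' members share the final alignment coordinates. Per-member distances
#' are the lattice distances between each projected member and the final
#' generalized sequence.
#'
#' @param seqs at least two sequences (named character vector or
#'   \code{DNAStringSet}) in ranked order: query first, then homologs by
#'   ascending alignment cost.
#' @param band see \code{\link{alignPair}}.
#' @param clusterId integer id stored in the record.
#' @param aligned if \code{TRUE} the members are already aligned (all
#'   equal length, gaps allowed) and are generalized column-wise as
#'   given; if \code{FALSE} (default) they are globally aligned by the
#'   built-in aligner as the fold proceeds.
#' @return An \code{\linkS4class{ObfuscationCluster}}.
#' @examples
#' cl <- obfuscateCluster(c(s1 = "CCTGTAAA", s2 = "CA-GTRAA"),
#'                        aligned = TRUE)
#' cl@generalizedSeq   # "CMNGTRAA"
#' cl@totalDistance    # 7
#' @export
obfuscateCluster <- function(seqs, band = 0L, clusterId = 1L,
                             aligned = FALSE) {
  seqs <- .asSeqSet(seqs)
  n <- length(seqs)
  if (n < 2L) stop("a cluster needs at least 2 sequences")
  ids <- names(seqs)
  if (aligned && length(unique(nchar(seqs))) != 1L)
    stop("aligned = TRUE requires members of equal length")

  pairAlign <- function(x, y) {
    if (aligned)
      list(xGapped = x, yGapped = y,
           ops = strrep("M", nchar(x)))
    else .alignRaw(x, y, band)
  }

  al <- pairAlign(seqs[[1L]], seqs[[2L]])
  alignedSeqs <- c(al$xGapped, al$yGapped)
  ob <- obfuscatePair(al$xGapped, al$yGapped)
  G <- ob$generalized
  events <- ob$events

  if (n > 2L) {
    for (m in 3L:n) {
      al <- pairAlign(G, seqs[[m]])
      opsv <- strsplit(al$ops, "", fixed = TRUE)[[1L]]
      ins <- which(opsv == "I")  # columns new to the G coordinates
      if (length(ins)) {
        alignedSeqs <- vapply(alignedSeqs, .insertGapCols, character(1),
                              ins = ins, USE.NAMES = FALSE)
        if (nrow(events)) {
          keep <- which(opsv != "I")
          events$column <- keep[events$column]
        }
      }
      alignedSeqs <- c(alignedSeqs, al$yGapped)
      ob <- obfuscatePair(al$xGapped, al$yGapped)
      G <- ob$generalized
      events <- rbind(events, ob$events)
    }
  }
  names(alignedSeqs) <- ids
  per <- vapply(alignedSeqs, sequenceDistance, integer(1), y = G)
  methods::new("ObfuscationCluster",
               clusterId = as.integer(clusterId), memberIds = ids,
               alignedMembers = alignedSeqs, generalizedSeq = G,
               perMemberDistance = per,
               totalDistance = as.integer(sum(per)),
               events = events[order(events$column), , drop = FALSE])
}

## Shared input checks for all clustering front ends.
.checkDataset <- function(seqs, k) {
  if (anyDuplicated(names(seqs)))
    stop("sequence identifiers must be unique")
  if (k < 2L) stop("k must be at least 2")
  if (length(seqs) < k)
    stop(sprintf("need at least k = %d sequences, got %d",
                 k, length(seqs)))
}

#' Iterative similarity-search clustering (IterMegaBLAST scheme)
#'
#' Clusters a dataset of highly similar DNA sequences into k-anonymous
#' groups by iterated similarity search: a query is drawn uniformly at
#' random (seeded) from the remaining sequences, its top k-1 homologs
#' within the remaining set are found by ranking alignment costs, the
#' query and homologs form a cluster and are obfuscated into one
#' generalized sequence, and the cluster is removed. When fewer than 2k
#' but at least k sequences remain they form the final cluster (for
#' k = 2 and odd N: the last three sequences, obfuscated by aligning the
#' second homolog against the previously obtained generalized sequence).
#'
#' The default backend is the built-in exact aligner
#' (\code{\link{rankHomologs}}); an external search tool can stand in
#' via \code{backend = "external"} and an \code{\link{adapterConfig}}.
#' Results are fully deterministic for a fixed (dataset order, k, seed).
#'
#' @param dataset named character vector or \code{DNAStringSet} with
#'   unique identifiers; at least k sequences.
#' @param k anonymity parameter (cluster size), at least 2.
#' @param seed integer seed for the random query draws.
#' @param band see \code{\link{alignPair}}.
#' @param backend \code{"builtin"} or \code{"external"}.
#' @param adapter an \code{\link{adapterConfig}}, required for the
#'   external backend.
#' @return A \code{\linkS4class{ClusteringResult}}.
#' @examples
#' ds <- c(a = "ACGTACGT", b = "ACGTACGA", c = "ACGTTCGT", d = "ACGTTCGA")
#' res <- iterMegablast(ds, k = 2, seed = 1)
#' clusterSizes(res)
#' @export
iterMegablast <- function(dataset, k = 2L, seed = 1L, band = 0L,
                          backend = c("builtin", "external"),
                          adapter = NULL) {
  backend <- match.arg(backend)
  seqs <- .asSeqSet(dataset)
  k <- as.integer(k)
  .checkDataset(seqs, k)
  if (backend == "external" && is.null(adapter))
    stop("backend = \"external\" requires an adapterConfig()")

  rankFun <- function(qi, rest) {
    db <- seqs[rest]
    hits <- if (backend == "builtin")
      rankHomologs(seqs[[qi]], db, band = band)
    else externalSearch(seqs[[qi]], db, adapter, band = band)
    match(hits$subjectId, names(seqs))
  }

  .withSeed(seed, function() {
    remaining <- seq_along(seqs)
    clusters <- list()
    cid <- 0L
    while (length(remaining) >= 2L * k) {
      qi <- remaining[sample.int(length(remaining), 1L)]
      rest <- setdiff(remaining, qi)
      ranked <- rankFun(qi, rest)
      members <- c(qi, ranked[seq_len(k - 1L)])
      cid <- cid + 1L
      clusters[[cid]] <- obfuscateCluster(seqs[members], band = band,
                                          clusterId = cid)
      remaining <- setdiff(remaining, members)
    }
    ## leftover cluster: k .. 2k-1 sequences, chained obfuscation
    qi <- remaining[sample.int(length(remaining), 1L)]
    rest <- setdiff(remaining, qi)
    members <- if (length(rest)) c(qi, rankFun(qi, rest)) else qi
    cid <- cid + 1L
    clusters[[cid]] <- obfuscateCluster(seqs[members], band = band,
                                        clusterId = cid)
    .newClusteringResult(clusters, "itermegablast", k, seed,
                         names(seqs))
  })
}

#' Degree of anonymity of a clustering result
#'
#' The privacy level implied by the smallest released cluster: with
#' minimum cluster size \code{k_min}, no individual can be re-identified
#' with probability greater than \code{1 / k_min}.
#'
#' @param result a \code{\linkS4class{ClusteringResult}}.
#' @return A list with \code{kMin} (smallest cluster size) and
#'   \code{reidentificationBound} (\code{1 / kMin}).
#' @export
degreeOfAnonymity <- function(result) {
  stopifnot(is(result, "ClusteringResult"))
  if (nClusters(result) == 0L) stop("empty clustering result")
  kMin <- min(clusterSizes(result))
  list(kMin = as.integer(kMin), reidentificationBound = 1 / kMin)
}
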