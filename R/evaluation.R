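# Evaluation harness: run the clustering methods repeatedly on a
# dataset and report both normalizations of the average obfuscation
# distance.

.METHOD_FUNS <- list(
  itermegablast = function(ds, k, seed, band)
    iterMegablast(ds, k = k, seed = seed, band = band),
  mwm = function(ds, k, seed, band) mwmCluster(ds, band = band),
  greedy = function(ds, k, seed, band) greedyCluster(ds, band = band),
  random = function(ds, k, seed, band)
    randomCluster(ds, seed = seed, band = band)
)
.STOCHASTIC <- c("itermegablast", "random")

#' Summary statistics of one clustering result
#'
#' @param result a \code{\linkS4class{ClusteringResult}}.
#' @return A one-row data.frame: \code{nSequences}, \code{nClusters},
#'   \code{totalDistance}, \code{avgPerSequence} (sum of per-member
#'   distances over N), \code{avgPerCluster} (sum of cluster totals over
#'   the number of clusters), \code{kMin}.
#' @export
resultReport <- function(result) {
  stopifnot(is(result, "ClusteringResult"))
  tot <- totalDistances(result)
  per <- perMemberDistances(result)
  data.frame(
    nSequences = length(result@inputIds),
    nClusters = nClusters(result),
    totalDistance = sum(tot),
    avgPerSequence = sum(per) / length(per),
    avgPerCluster = sum(tot) / length(tot),
    kMin = min(clusterSizes(result)))
}

#' Compare clustering methods on one dataset
#'
#' Runs each requested method on the dataset and reports the mean and
#' standard deviation of the average obfuscation distance under both
#' normalizations (per sequence and per cluster). Stochastic methods
#' (\code{"itermegablast"}, \code{"random"}) are run \code{repeats}
#' times with derived seeds \code{seed, seed + 1, ...}; deterministic
#' methods (\code{"mwm"}, \code{"greedy"}) are run once and reported
#' with zero standard deviation.
#'
#' @param dataset named character vector or \code{DNAStringSet}.
#' @param methods subset of \code{"itermegablast"}, \code{"mwm"},
#'   \code{"greedy"}, \code{"random"}.
#' @param k anonymity parameter; the matching baselines are defined for
#'   \code{k = 2} only.
#' @param repeats number of repetitions for stochastic methods (>= 1).
#' @param seed base seed.
#' @param band see \code{\link{alignPair}}.
#' @return A data.frame with one row per method: \code{method},
#'   \code{nSequences}, \code{k}, \code{repeats}, \code{seed},
#'   \code{meanPerSequence}, \code{sdPerSequence},
#'   \code{meanPerCluster}, \code{sdPerCluster}, \code{kMin}.
#' @export
evaluateMethods <- function(dataset,
                            methods = c("itermegablast", "mwm",
                                        "greedy"),
                            k = 2L, repeats = 10L, seed = 1L,
                            band = 0L) {
  unknown <- setdiff(methods, names(.METHOD_FUNS))
  if (length(unknown))
    stop("unknown method tag(s): ", paste(unknown, collapse = ", "))
  if (repeats < 1L) stop("repeats must be >= 1")
  k <- as.integer(k)
  if (k != 2L && any(methods %in% c("mwm", "greedy", "random")))
    stop("the pairing baselines are defined for k = 2 only")
  seqs <- .asSeqSet(dataset)

  rows <- lapply(methods, function(m) {
    reps <- if (m %in% .STOCHASTIC) as.integer(repeats) else 1L
    seeds <- seed + seq_len(reps) - 1L
    reports <- lapply(seeds, function(s)
      resultReport(.METHOD_FUNS[[m]](seqs, k, s, band)))
    perSeq <- vapply(reports, `[[`, numeric(1), "avgPerSequence")
    perClu <- vapply(reports, `[[`, numeric(1), "avgPerCluster")
    data.frame(
      method = m, nSequences = length(seqs), k = k, repeats = reps,
      seed = seed,
      meanPerSequence = mean(perSeq),
      sdPerSequence = if (reps > 1L) stats::sd(perSeq) else 0,
      meanPerCluster = mean(perClu),
      sdPerCluster = if (reps > 1L) stats::sd(perClu) else 0,
      kMin = min(vapply(reports, `[[`, numeric(1), "kMin")))
  })
  do.call(rbind, rows)
}

#' Evaluate methods across dataset sizes
#'
#' Subsamples the dataset at each requested size and runs
#' \code{\link{evaluateMethods}}, producing a tidy table of average
#' distances versus the number of sequences. By default the first
#' \code{n} sequences are taken (deterministic); with
#' \code{randomSubset = TRUE} a seeded random subset is drawn per size.
#'
#' @inheritParams evaluateMethods
#' @param nValues integer vector of dataset sizes, each at most the
#'   dataset size.
#' @param randomSubset draw a seeded random subset instead of the
#'   deterministic prefix.
#' @return A data.frame: the \code{\link{evaluateMethods}} columns plus
#'   a leading \code{n}.
#' @export
sweepN <- function(dataset, nValues,
                   methods = c("itermegablast", "mwm", "greedy"),
                   k = 2L, repeats = 10L, seed = 1L, band = 0L,
                   randomSubset = FALSE) {
  seqs <- .asSeqSet(dataset)
  if (any(nValues > length(seqs)))
    stop(sprintf("requested n = %d exceeds dataset size %d",
                 max(nValues), length(seqs)))
  rows <- lapply(nValues, function(n) {
    idx <- if (randomSubset)
      .withSeed(seed + n, function() sort(sample.int(length(seqs), n)))
    else seq_len(n)
    cbind(n = n,
          evaluateMethods(seqs[idx], methods = methods, k = k,
                          repeats = repeats, seed = seed, band = band))
  })
  do.call(rbind, rows)
}
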