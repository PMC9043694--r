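# S4 containers for alignments, obfuscated clusters and clustering results.

#' PairAlignment: a global alignment of two sequences
#'
#' Holds the two equal-length gapped strings of a pairwise global
#' alignment, the operation string (\code{M} = both residues, \code{D} =
#' left residue vs gap, \code{I} = gap vs right residue) and the total
#' lattice-distance cost of the alignment. The cost always equals
#' \code{\link{sequenceDistance}} of the two gapped strings.
#'
#' @slot leftId,rightId sequence identifiers.
#' @slot leftGapped,rightGapped equal-length gapped strings.
#' @slot ops per-column operation string.
#' @slot cost total lattice distance (integer).
#' @seealso \code{\link{alignPair}}
#' @export
setClass("PairAlignment",
  slots = c(leftId = "character", rightId = "character",
            leftGapped = "character", rightGapped = "character",
            ops = "character", cost = "integer"),
  validity = function(object) {
    msg <- character()
    if (nchar(object@leftGapped) != nchar(object@rightGapped))
      msg <- c(msg, "gapped strings differ in length")
    if (nchar(object@ops) != nchar(object@leftGapped))
      msg <- c(msg, "ops string length does not match alignment length")
    if (grepl("[^MDI]", object@ops))
      msg <- c(msg, "ops may only contain M, D, I")
    if (length(msg) == 0 &&
        object@cost != sequenceDistance(object@leftGapped,
                                        object@rightGapped))
      msg <- c(msg, "cost does not equal the lattice distance")
    if (length(msg)) msg else TRUE
  })

#' ObfuscationCluster: one k-anonymous cluster and its release
#'
#' One cluster of sequences together with its generalized (obfuscated)
#' sequence, the members projected into the final alignment coordinates,
#' per-member lattice distances to the generalized sequence, and the
#' per-column generalization events.
#'
#' @slot clusterId integer cluster id.
#' @slot memberIds identifiers of the member sequences (>= 2).
#' @slot alignedMembers gapped member strings in the coordinates of the
#'   generalized sequence, named by member id.
#' @slot generalizedSeq the released generalized sequence.
#' @slot perMemberDistance named integer vector: lattice distance of each
#'   aligned member to the generalized sequence.
#' @slot totalDistance sum of the per-member distances.
#' @slot events data.frame of generalization events with columns
#'   \code{column} (1-based alignment column), \code{left}, \code{right},
#'   \code{generalized}, \code{cost}; only columns with positive cost are
#'   recorded.
#' @export
setClass("ObfuscationCluster",
  slots = c(clusterId = "integer", memberIds = "character",
            alignedMembers = "character", generalizedSeq = "character",
            perMemberDistance = "integer", totalDistance = "integer",
            events = "data.frame"),
  validity = function(object) {
    msg <- character()
    n <- length(object@memberIds)
    if (n < 2L) msg <- c(msg, "a cluster needs at least 2 members")
    if (length(object@alignedMembers) != n ||
        !identical(names(object@alignedMembers), object@memberIds))
      msg <- c(msg, "alignedMembers must be named by memberIds")
    if (length(object@perMemberDistance) != n ||
        !identical(names(object@perMemberDistance), object@memberIds))
      msg <- c(msg, "perMemberDistance must be named by memberIds")
    L <- nchar(object@generalizedSeq)
    if (any(nchar(object@alignedMembers) != L))
      msg <- c(msg, "aligned members and generalized sequence differ in length")
    if (object@totalDistance != sum(object@perMemberDistance))
      msg <- c(msg, "totalDistance must equal the sum of per-member distances")
    if (length(msg)) msg else TRUE
  })

#' ClusteringResult: a k-anonymous partition with obfuscated releases
#'
#' The result of a clustering method: a partition of the input sequences
#' into clusters of size at least k (all of size exactly k except at most
#' one leftover cluster of size k+1 .. 2k-1 when N is not a multiple of
#' k), each with its \code{\linkS4class{ObfuscationCluster}} record.
#'
#' @slot clusters list of \code{\linkS4class{ObfuscationCluster}}.
#' @slot method method tag (\code{"itermegablast"}, \code{"mwm"},
#'   \code{"greedy"} or \code{"random"}).
#' @slot k the anonymity parameter.
#' @slot seed the seed used (NA for deterministic methods).
#' @slot inputIds identifiers of the input sequences, in input order.
#' @export
setClass("ClusteringResult",
  slots = c(clusters = "list", method = "character", k = "integer",
            seed = "integer", inputIds = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(vapply(object@clusters, is, logical(1),
                    class2 = "ObfuscationCluster")))
      return("clusters must all be ObfuscationCluster objects")
    members <- unlist(lapply(object@clusters, slot, "memberIds"),
                      use.names = FALSE)
    if (anyDuplicated(members))
      msg <- c(msg, "a sequence appears in more than one cluster")
    if (!setequal(members, object@inputIds))
      msg <- c(msg, "cluster members do not partition the input ids")
    sizes <- vapply(object@clusters, function(cl)
      length(cl@memberIds), integer(1))
    k <- object@k
    if (length(sizes) && min(sizes) < k)
      msg <- c(msg, sprintf("cluster smaller than k = %d found", k))
    big <- sizes > k
    if (sum(big) > 1L || (any(big) && sizes[big] > 2L * k - 1L))
      msg <- c(msg,
               "only one leftover cluster of size at most 2k-1 is allowed")
    if (length(msg)) msg else TRUE
  })

.newClusteringResult <- function(clusters, method, k, seed, inputIds) {
  methods::new("ClusteringResult", clusters = clusters, method = method,
               k = as.integer(k), seed = as.integer(seed),
               inputIds = inputIds)
}

## ---- show methods ---------------------------------------------------

setMethod("show", "PairAlignment", function(object) {
  trunc1 <- function(s) if (nchar(s) > 60)
    paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("PairAlignment: %s vs %s\n", object@leftId, object@rightId))
  cat(sprintf("  length %d, lattice cost %d\n",
              nchar(object@leftGapped), object@cost))
  cat("  ", trunc1(object@leftGapped), "\n  ",
      trunc1(object@rightGapped), "\n", sep = "")
})

setMethod("show", "ObfuscationCluster", function(object) {
  cat(sprintf("ObfuscationCluster #%d: %d members, total distance %d\n",
              object@clusterId, length(object@memberIds),
              object@totalDistance))
  cat("  members:", paste(object@memberIds, collapse = ", "), "\n")
  cat(sprintf("  %d generalization event(s) over %d columns\n",
              nrow(object@events), nchar(object@generalizedSeq)))
})

setMethod("show", "ClusteringResult", function(object) {
  sizes <- clusterSizes(object)
  cat(sprintf(
    "ClusteringResult (%s): %d sequences in %d clusters (k = %d%s)\n",
    object@method, length(object@inputIds), length(object@clusters),
    object@k,
    if (is.na(object@seed)) "" else sprintf(", seed = %d", object@seed)))
  cat(sprintf("  cluster sizes: %s; total distance %d\n",
              paste(sizes, collapse = " "),
              sum(totalDistances(object))))
})

## ---- generics and accessors -----------------------------------------

#' @name accessors
#' @title Accessors for clustering results
#' @description Accessor generics for
#'   \code{\linkS4class{ClusteringResult}} and
#'   \code{\linkS4class{PairAlignment}} objects.
#' @param object,x a seqanon S4 object.
#' @return \code{nClusters}: integer; \code{clusterSizes},
#'   \code{totalDistances}: integer vectors; \code{memberIds}: list of
#'   character vectors (or character vector for a single cluster);
#'   \code{methodName}: character; \code{anonymityK}: integer;
#'   \code{generalizedSequences}: a \code{DNAStringSet};
#'   \code{perMemberDistances}: named integer vector over all input
#'   sequences; \code{clusterRecords}: list of
#'   \code{ObfuscationCluster}; \code{metaTable}: data.frame (the
#'   machine-readable "meta info"); \code{alignmentCost}: integer;
#'   \code{gappedStrings}: named character vector of length 2.
NULL

#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))
#' @rdname accessors
#' @export
setGeneric("memberIds", function(object) standardGeneric("memberIds"))
#' @rdname accessors
#' @export
setGeneric("methodName", function(object) standardGeneric("methodName"))
#' @rdname accessors
#' @export
setGeneric("anonymityK", function(object) standardGeneric("anonymityK"))
#' @rdname accessors
#' @export
setGeneric("totalDistances",
           function(object) standardGeneric("totalDistances"))
#' @rdname accessors
#' @export
setGeneric("perMemberDistances",
           function(object) standardGeneric("perMemberDistances"))
#' @rdname accessors
#' @export
setGeneric("generalizedSequences",
           function(object) standardGeneric("generalizedSequences"))
#' @rdname accessors
#' @export
setGeneric("clusterRecords",
           function(object) standardGeneric("clusterRecords"))
#' @rdname accessors
#' @export
setGeneric("metaTable", function(object) standardGeneric("metaTable"))
#' @rdname accessors
#' @export
setGeneric("alignmentCost",
           function(object) standardGeneric("alignmentCost"))
#' @rdname accessors
#' @export
setGeneric("gappedStrings",
           function(object) standardGeneric("gappedStrings"))

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusteringResult",
          function(object) length(object@clusters))

#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusteringResult", function(object)
  vapply(object@clusters, function(cl) length(cl@memberIds), integer(1)))

#' @rdname accessors
#' @export
setMethod("memberIds", "ClusteringResult", function(object)
  lapply(object@clusters, slot, "memberIds"))

#' @rdname accessors
#' @export
setMethod("memberIds", "ObfuscationCluster",
          function(object) object@memberIds)

#' @rdname accessors
#' @export
setMethod("methodName", "ClusteringResult",
          function(object) object@method)

#' @rdname accessors
#' @export
setMethod("anonymityK", "ClusteringResult", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("totalDistances", "ClusteringResult", function(object)
  vapply(object@clusters, slot, integer(1), "totalDistance"))

#' @rdname accessors
#' @export
setMethod("perMemberDistances", "ClusteringResult", function(object)
  unlist(lapply(object@clusters, slot, "perMemberDistance")))

#' @rdname accessors
#' @export
setMethod("generalizedSequences", "ClusteringResult", function(object) {
  seqs <- vapply(object@clusters, slot, character(1), "generalizedSeq")
  names(seqs) <- sprintf("cluster_%d", vapply(object@clusters, slot,
                                              integer(1), "clusterId"))
  Biostrings::DNAStringSet(seqs)
})

#' @rdname accessors
#' @export
setMethod("clusterRecords", "ClusteringResult",
          function(object) object@clusters)

#' @rdname accessors
#' @export
setMethod("metaTable", "ClusteringResult",
          function(object) .buildMetaTable(object))

#' @rdname accessors
#' @export
setMethod("alignmentCost", "PairAlignment",
          function(object) object@cost)

#' @rdname accessors
#' @export
setMethod("gappedStrings", "PairAlignment", function(object)
  stats::setNames(c(object@leftGapped, object@rightGapped),
                  c(object@leftId, object@rightId)))
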