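# Input coercion and FASTA / meta-info output.

## Coerce a sequence set (DNAStringSet, character vector, or list) to a
## named character vector; missing names are auto-filled.
.asSeqSet <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.list(x)) {
    out <- vapply(x, .asSingleSeq, character(1))
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected a DNAStringSet, character vector or list of sequences")
  }
  if (is.null(names(out)) || any(!nzchar(names(out))) ||
      anyNA(names(out))) {
    nm <- names(out)
    if (is.null(nm)) nm <- rep("", length(out))
    fix <- !nzchar(nm) | is.na(nm)
    nm[fix] <- sprintf("seq%d", which(fix))
    names(out) <- nm
  }
  out
}

#' Read a DNA FASTA file
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} that truncates
#' FASTA headers at the first whitespace so identifiers are short and
#' unique-checkable.
#'
#' @param path path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return A named \code{DNAStringSet}.
#' @export
readFastaDna <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write the obfuscated release as multi-FASTA
#'
#' Writes one record per cluster: the generalized sequence, with a header
#' carrying the cluster id, the method tag, k, and the member ids.
#'
#' @param result a \code{\linkS4class{ClusteringResult}}.
#' @param file output path.
#' @return Invisibly, the output path.
#' @export
writeObfuscatedFasta <- function(result, file) {
  stopifnot(is(result, "ClusteringResult"))
  seqs <- vapply(result@clusters, slot, character(1), "generalizedSeq")
  names(seqs) <- vapply(result@clusters, function(cl) sprintf(
    "cluster_%d method=%s;k=%d;members=%s", cl@clusterId,
    result@method, result@k, paste(cl@memberIds, collapse = ",")),
    character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(file)
}

## One tab-separated table: cluster-level columns repeated on every
## event row; clusters without events get a single row with NA events.
.buildMetaTable <- function(result) {
  rows <- lapply(result@clusters, function(cl) {
    ev <- cl@events
    if (nrow(ev) == 0L)
      ev <- data.frame(column = NA_integer_, left = NA_character_,
                       right = NA_character_,
                       generalized = NA_character_,
                       cost = NA_integer_)
    data.frame(
      cluster_id = cl@clusterId,
      method = result@method,
      k = result@k,
      member_ids = paste(cl@memberIds, collapse = ","),
      per_member_distance = paste(
        sprintf("%s=%d", names(cl@perMemberDistance),
                cl@perMemberDistance), collapse = ","),
      total_distance = cl@totalDistance,
      event_column = ev$column,
      event_left = ev$left,
      event_right = ev$right,
      event_generalized = ev$generalized,
      event_cost = ev$cost,
      row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write the cluster meta-information table
#'
#' Writes the machine-readable counterpart of each cluster's "meta info":
#' per cluster its id, member ids, per-member and total distances, and
#' one row per generalization event (alignment column, the two original
#' symbols, the generalized symbol, and the column cost).
#'
#' @inheritParams writeObfuscatedFasta
#' @return Invisibly, the output path.
#' @seealso \code{\link{readMetaInfo}}, \code{\link{reportFromMeta}}
#' @export
writeMetaInfo <- function(result, file) {
  stopifnot(is(result, "ClusteringResult"))
  utils::write.table(.buildMetaTable(result), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a cluster meta-information table
#'
#' @param file path written by \code{\link{writeMetaInfo}}.
#' @return The meta table as a data.frame.
#' @export
readMetaInfo <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Re-derive summary statistics from a meta table
#'
#' Recomputes, from a (written and re-read) meta-information table alone,
#' the quantities reported by \code{\link{evaluateMethods}}: the average
#' distance per sequence (sum of per-member distances over the number of
#' sequences) and per cluster (sum of cluster totals over the number of
#' clusters).
#'
#' @param meta a data.frame from \code{\link{readMetaInfo}}.
#' @return A one-row data.frame with \code{nSequences}, \code{nClusters},
#'   \code{totalDistance}, \code{avgPerSequence}, \code{avgPerCluster}.
#' @export
reportFromMeta <- function(meta) {
  first <- meta[!duplicated(meta$cluster_id), , drop = FALSE]
  per <- unlist(lapply(strsplit(first$per_member_distance, ","),
                       function(x) as.integer(sub("^.*=", "", x))))
  data.frame(
    nSequences = length(per),
    nClusters = nrow(first),
    totalDistance = sum(first$total_distance),
    avgPerSequence = sum(per) / length(per),
    avgPerCluster = sum(first$total_distance) / nrow(first))
}
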