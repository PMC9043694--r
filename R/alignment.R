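# Pairwise global alignment under the lattice cost model, similarity
# ranking, and the external search-tool adapter.

#' @include lattice.R
NULL

.COST_ALPHABET <- paste(LATTICE_ALPHABET, collapse = "")
.GAP_IDX0 <- match("-", LATTICE_ALPHABET) - 1L  # 0-based for C++

## Thin wrapper around the compiled DP; returns list(cost, ops, xGapped,
## yGapped). Both inputs are plain strings.
.alignRaw <- function(x, y, band = 0L) {
  if (nchar(x) == 0L || nchar(y) == 0L)
    stop("cannot align an empty sequence")
  .alignCoreCpp(x, y, .DIST, .COST_ALPHABET, .GAP_IDX0,
                as.integer(band))
}

#' Global alignment of two sequences under the lattice cost
#'
#' Computes an exact global alignment of two extended-alphabet DNA
#' sequences that minimizes the total obfuscation information loss: a
#' substitution column costs the lattice distance of its two symbols and
#' a residue aligned against a gap costs its lattice distance to
#' \code{"-"} (4 for a base, less for ambiguity codes). Because the
#' aligner minimizes exactly the distance that obfuscation will incur,
#' the alignment cost of a pair equals the total information loss of
#' releasing that pair as one generalized sequence.
#'
#' Tie-breaking in the dynamic program is fixed (diagonal, then gap in
#' the right sequence, then gap in the left sequence), so results are
#' fully deterministic. An optional band (for long, highly similar
#' sequences) restricts the matrix to cells within \code{band +
#' abs(nchar(x) - nchar(y))} of the diagonal; the default \code{band =
#' 0} computes the full matrix and is always exact.
#'
#' @param x,y sequences: single character strings, \code{DNAString}s, or
#'   length-1 named \code{DNAStringSet}s.
#' @param xId,yId identifiers; defaults to the names of \code{x}/\code{y}
#'   or \code{"x"}/\code{"y"}.
#' @param band integer half-width of the alignment band; \code{0} for the
#'   full (exact) matrix.
#' @return A \code{\linkS4class{PairAlignment}}.
#' @examples
#' al <- alignPair("ACGT", "ACGGT")
#' alignmentCost(al)   # 4: one base against a gap
#' gappedStrings(al)
#' @export
alignPair <- function(x, y, xId = NULL, yId = NULL, band = 0L) {
  if (is.null(xId))
    xId <- if (!is.null(names(x))) names(x)[1] else "x"
  if (is.null(yId))
    yId <- if (!is.null(names(y))) names(y)[1] else "y"
  xs <- .asSingleSeq(x)
  ys <- .asSingleSeq(y)
  al <- .alignRaw(xs, ys, band)
  methods::new("PairAlignment", leftId = xId, rightId = yId,
               leftGapped = al$xGapped, rightGapped = al$yGapped,
               ops = al$ops, cost = as.integer(al$cost))
}

#' Rank database sequences by similarity to a query
#'
#' Aligns the query against every database sequence with
#' \code{\link{alignPair}} and ranks the subjects by ascending alignment
#' cost; ties are broken by ascending position in the database. This is
#' the built-in stand-in for an external similarity-search tool: the
#' rank-1 subject is the query's top homolog.
#'
#' @param query a single sequence.
#' @param database a named character vector or \code{DNAStringSet} of
#'   candidate subjects (non-empty).
#' @param band see \code{\link{alignPair}}.
#' @return A data.frame with columns \code{subjectId}, \code{cost},
#'   \code{rank}, ordered by rank.
#' @export
rankHomologs <- function(query, database, band = 0L) {
  db <- .asSeqSet(database)
  if (length(db) == 0L) stop("database must contain at least one sequence")
  q <- .asSingleSeq(query)
  costs <- vapply(db, function(s) .alignRaw(q, s, band)$cost, numeric(1))
  ord <- order(costs, seq_along(costs))
  data.frame(subjectId = names(db)[ord],
             cost = as.integer(costs[ord]),
             rank = seq_along(ord),
             row.names = NULL)
}

#' Configuration for an external similarity-search backend
#'
#' Describes how to invoke an external nucleotide search tool (e.g. a
#' seed-and-extend aligner run in query-vs-subject mode) whose tabular
#' output provides candidate homologs. The command is built from
#' \code{args} by substituting \code{{query}} and \code{{subject}} with
#' paths to temporary FASTA files; the subject identifier is read from
#' column \code{subjectColumn} of the tab-separated output.
#'
#' @param path executable name or path.
#' @param args character vector of arguments with \code{{query}} /
#'   \code{{subject}} placeholders. The default invokes a BLAST-style
#'   tool in megablast mode with tabular output.
#' @param subjectColumn 1-based column of the subject id in the output.
#' @return An object of class \code{"seqanonAdapter"}.
#' @export
adapterConfig <- function(path,
                          args = c("-task", "megablast",
                                   "-query", "{query}",
                                   "-subject", "{subject}",
                                   "-outfmt", "6"),
                          subjectColumn = 2L) {
  structure(list(path = path, args = args,
                 subjectColumn = as.integer(subjectColumn)),
            class = "seqanonAdapter")
}

#' Similarity search through an external tool
#'
#' Runs the configured external search executable on a query against a
#' database and converts its hits to the same ranking contract as
#' \code{\link{rankHomologs}}: one row per database sequence, ranked by
#' ascending built-in alignment cost with ties broken by database order.
#' Subjects the external tool reports are ranked first; subjects missing
#' from its output are appended afterwards (ranked among themselves the
#' same way), so a complete ranking is always returned.
#'
#' @param query a single sequence.
#' @param database named character vector or \code{DNAStringSet}.
#' @param config an \code{\link{adapterConfig}} object.
#' @param band band width for the built-in cost computation.
#' @return A data.frame with columns \code{subjectId}, \code{cost},
#'   \code{rank}.
#' @export
externalSearch <- function(query, database, config, band = 0L) {
  if (!inherits(config, "seqanonAdapter"))
    stop("config must be created with adapterConfig()")
  exe <- config$path
  resolved <- Sys.which(exe)
  if (!nzchar(resolved)) {
    if (file.exists(exe) && file.access(exe, 1L) == 0L) resolved <- exe
    else stop("external search executable '", exe, "' not found or not ",
              "executable; use the built-in backend (rankHomologs) instead")
  }
  db <- .asSeqSet(database)
  if (length(db) == 0L) stop("database must contain at least one sequence")
  q <- .asSingleSeq(query)

  qf <- tempfile(fileext = ".fa")
  sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  writeLines(c(">query", q), qf)
  writeLines(as.vector(rbind(paste0(">", names(db)), unname(db))), sf)

  args <- gsub("{query}", qf, config$args, fixed = TRUE)
  args <- gsub("{subject}", sf, args, fixed = TRUE)
  out <- suppressWarnings(system2(resolved, args, stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("external search executable '", exe, "' exited with status ",
         status, "; use the built-in backend (rankHomologs) instead")

  hit <- character(0)
  if (length(out)) {
    fields <- strsplit(out, "\t", fixed = TRUE)
    hit <- unique(vapply(fields, function(f)
      if (length(f) >= config$subjectColumn) f[config$subjectColumn]
      else NA_character_, character(1)))
    hit <- hit[!is.na(hit) & hit %in% names(db)]
  }
  miss <- setdiff(names(db), hit)

  rankBlock <- function(ids) {
    if (!length(ids)) return(NULL)
    idx <- match(ids, names(db))
    costs <- vapply(db[idx], function(s) .alignRaw(q, s, band)$cost,
                    numeric(1))
    ord <- order(costs, idx)
    data.frame(subjectId = ids[ord], cost = as.integer(costs[ord]),
               row.names = NULL)
  }
  res <- rbind(rankBlock(hit), rankBlock(miss))
  res$rank <- seq_len(nrow(res))
  res
}
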