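# Seeded synthetic-dataset simulator: N sequences derived independently
# from one random reference by point substitutions, short indels and
# occasional ambiguity (N) symbols.

#' SimConfig: synthetic dataset configuration
#'
#' @slot nSequences number of sequences to derive (>= 2).
#' @slot length reference length in nucleotides (>= 1).
#' @slot substitutionRate per-site probability of a point substitution.
#' @slot indelRate per-site probability of an indel event (insertion or
#'   deletion with equal probability; length geometric with mean 2).
#' @slot ambiguityRate per-site probability a site is replaced by N.
#' @slot gcBias named base-composition weights (A, C, G, T; sum to 1).
#' @slot seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @export
setClass("SimConfig",
  slots = c(nSequences = "integer", length = "integer",
            substitutionRate = "numeric", indelRate = "numeric",
            ambiguityRate = "numeric", gcBias = "numeric",
            seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSequences < 2L) msg <- c(msg, "nSequences must be >= 2")
    if (object@length < 1L) msg <- c(msg, "length must be >= 1")
    for (r in c("substitutionRate", "indelRate", "ambiguityRate")) {
      v <- slot(object, r)
      if (length(v) != 1L || is.na(v) || v < 0 || v >= 1)
        msg <- c(msg, paste(r, "must be a single value in [0, 1)"))
    }
    if (!identical(sort(names(object@gcBias)),
                   c("A", "C", "G", "T")) ||
        any(object@gcBias < 0) ||
        abs(sum(object@gcBias) - 1) > 1e-8)
      msg <- c(msg, "gcBias must be named weights for A, C, G, T summing to 1")
    if (length(msg)) msg else TRUE
  })

#' Create a synthetic dataset configuration
#'
#' @param nSequences,length,substitutionRate,indelRate,ambiguityRate,gcBias,seed
#'   see \code{\linkS4class{SimConfig}}.
#' @return A validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(10, 200, substitutionRate = 0.01, seed = 42)
#' @export
simConfig <- function(nSequences, length, substitutionRate = 0.01,
                      indelRate = 0, ambiguityRate = 0,
                      gcBias = c(A = 0.25, C = 0.25, G = 0.25,
                                 T = 0.25),
                      seed = 1L) {
  methods::new("SimConfig", nSequences = as.integer(nSequences),
               length = as.integer(length),
               substitutionRate = substitutionRate,
               indelRate = indelRate, ambiguityRate = ambiguityRate,
               gcBias = gcBias[c("A", "C", "G", "T")],
               seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d sequences, reference %d nt, sub %.4g, indel %.4g, N %.4g, seed %d\n",
    object@nSequences, object@length, object@substitutionRate,
    object@indelRate, object@ambiguityRate, object@seed))
  cat("  composition:", paste(sprintf("%s=%.2f", names(object@gcBias),
                                      object@gcBias), collapse = " "),
      "\n")
})

.BASES <- c("A", "C", "G", "T")

## Derive one mutant from the reference (a character vector of bases).
.mutateReference <- function(ref, cfg) {
  L <- length(ref)
  mut <- ref
  sub <- which(stats::runif(L) < cfg@substitutionRate)
  for (s in sub)
    mut[s] <- sample(setdiff(.BASES, mut[s]), 1L)
  amb <- which(stats::runif(L) < cfg@ambiguityRate)
  mut[amb] <- "N"
  if (cfg@indelRate > 0) {
    sites <- which(stats::runif(L) < cfg@indelRate)
    for (s in rev(sites)) {       # descending: later edits keep indices valid
      len <- stats::rgeom(1L, 0.5) + 1L
      if (stats::runif(1L) < 0.5) {
        mut <- mut[-(s:min(s + len - 1L, length(mut)))]
      } else {
        ins <- sample(.BASES, len, replace = TRUE, prob = cfg@gcBias)
        mut <- append(mut, ins, after = s)
      }
    }
  }
  if (length(mut) == 0L) mut <- sample(.BASES, 1L, prob = cfg@gcBias)
  mut
}

#' Simulate a synthetic dataset of highly similar sequences
#'
#' Draws one random reference sequence from the configured base
#' composition, then derives each dataset sequence independently from
#' that reference (star topology) by per-site substitutions, short
#' indels (geometric lengths, mean 2) and N-masking at the configured
#' rates. The output is a deterministic function of the configuration,
#' including its seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A named \code{DNAStringSet} of \code{nSequences} sequences.
#' @examples
#' ds <- simulateDataset(simConfig(5, 100, substitutionRate = 0.02,
#'                                 seed = 7))
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  .withSeed(config@seed, function() {
    ref <- sample(.BASES, config@length, replace = TRUE,
                  prob = config@gcBias)
    seqs <- vapply(seq_len(config@nSequences), function(i)
      paste(.mutateReference(ref, config), collapse = ""),
      character(1))
    names(seqs) <- sprintf("seq%03d", seq_len(config@nSequences))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Built-in dataset regimes
#'
#' Two preset configurations emulating the benchmark regimes the method
#' targets: \code{"dataset1-like"}, a small set of long promoter-locus
#' sequences (56 sequences of 6580 nt, G-enriched, low diversity and few
#' ambiguity symbols), and \code{"dataset2-like"}, a large set of short
#' mitochondrial control-region sequences (372 sequences of 500 nt,
#' C-enriched, hypervariable-level diversity and a markedly higher rate
#' of N symbols).
#'
#' @return A named list of \code{\linkS4class{SimConfig}} objects.
#' @export
simPresets <- function() {
  list(
    `dataset1-like` = simConfig(
      nSequences = 56L, length = 6580L, substitutionRate = 0.002,
      indelRate = 5e-4, ambiguityRate = 2e-4,
      gcBias = c(A = 0.22, C = 0.24, G = 0.32, T = 0.22), seed = 101L),
    `dataset2-like` = simConfig(
      nSequences = 372L, length = 500L, substitutionRate = 0.01,
      indelRate = 1e-3, ambiguityRate = 2e-3,
      gcBias = c(A = 0.30, C = 0.35, G = 0.13, T = 0.22), seed = 202L))
}

#' Fetch a preset configuration, optionally rescaled
#'
#' Returns one of the \code{\link{simPresets}} with selected fields
#' overridden (typically \code{nSequences} or \code{seed} to run the
#' same regime at a smaller scale or with a different draw). Mutation
#' rates and composition are part of the regime and are not meant to be
#' changed this way.
#'
#' @param name preset name (\code{"dataset1-like"} or
#'   \code{"dataset2-like"}).
#' @param nSequences,length,seed optional overrides.
#' @return A \code{\linkS4class{SimConfig}}.
#' @export
presetConfig <- function(name, nSequences = NULL, length = NULL,
                         seed = NULL) {
  presets <- simPresets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  cfg <- presets[[name]]
  if (!is.null(nSequences)) cfg@nSequences <- as.integer(nSequences)
  if (!is.null(length)) cfg@length <- as.integer(length)
  if (!is.null(seed)) cfg@seed <- as.integer(seed)
  methods::validObject(cfg)
  cfg
}
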