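#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet DNAString
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Synthetic phage community with ground truth
#'
#' Container for the output of [simulateCommunity()]: the planted genomes,
#' the simulated shotgun read set, and the truth tables that tie every read
#' and genome back to its phylotype and every genome to its ORF layout.
#'
#' @slot genomes [Biostrings::DNAStringSet] of planted (possibly 5'-truncated)
#'   genome variants.
#' @slot features data.frame of ancestral ORF coordinates per genome
#'   (columns `genome`, `role`, `start`, `end`, `strand`; 0-based half-open).
#' @slot reads [Biostrings::DNAStringSet] of simulated shotgun reads.
#' @slot readTruth data.frame mapping every read to its source genome,
#'   phylotype (or `"background"`), start position and strand.
#' @slot genomeTruth data.frame mapping every genome to its phylotype and
#'   length.
#' @slot spec list echoing the generating [communitySpec()].
#'
#' @seealso [simulateCommunity()], [communitySpec()]
#' @export
setClass("PhageCommunity",
  representation(
    genomes = "DNAStringSet",
    features = "data.frame",
    reads = "DNAStringSet",
    readTruth = "data.frame",
    genomeTruth = "data.frame",
    spec = "list"
  )
)

setValidity("PhageCommunity", function(object) {
  msg <- character()
  if (!all(names(object@reads) %in% object@readTruth$read)) {
    msg <- c(msg, "every read must have exactly one truth record")
  }
  if (anyDuplicated(object@readTruth$read)) {
    msg <- c(msg, "duplicated read truth records")
  }
  if (!all(names(object@genomes) %in% object@genomeTruth$genome)) {
    msg <- c(msg, "every genome must have a truth record")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PhageCommunity planted genomes
#' @param x,object a `PhageCommunity`
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @export
setMethod("genomes", "PhageCommunity", function(x) x@genomes)

#' @describeIn PhageCommunity simulated reads
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @export
setMethod("reads", "PhageCommunity", function(x) x@reads)

#' @describeIn PhageCommunity read-level truth table
#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))

#' @export
setMethod("readTruth", "PhageCommunity", function(x) x@readTruth)

#' @describeIn PhageCommunity genome-level truth table
#' @export
setGeneric("genomeTruth", function(x) standardGeneric("genomeTruth"))

#' @export
setMethod("genomeTruth", "PhageCommunity", function(x) x@genomeTruth)

#' @describeIn PhageCommunity ancestral ORF features
#' @export
setGeneric("communityFeatures", function(x) standardGeneric("communityFeatures"))

#' @export
setMethod("communityFeatures", "PhageCommunity", function(x) x@features)

setMethod("show", "PhageCommunity", function(object) {
  cat("PhageCommunity\n")
  cat("  phylotypes: ", length(unique(object@genomeTruth$phylotype)), "\n",
      sep = "")
  cat("  genomes:    ", length(object@genomes), "\n", sep = "")
  cat("  reads:      ", length(object@reads),
      " (", sum(object@readTruth$phylotype == "background"),
      " background)\n", sep = "")
})

#' Pairwise identity matrix with mismatch counts
#'
#' Symmetric pairwise identity over a set of named sequences, carrying for
#' every pair the fraction of identical columns, the mismatch count, and the
#' number of aligned positions (columns where both sequences place an
#' unambiguous residue; gaps are deleted pairwise, following the p-distance
#' convention). Rendered tables put identities in the upper triangle and
#' mismatch counts in the lower triangle.
#'
#' @slot identity numeric matrix of pairwise identities in `[0, 1]`.
#' @slot mismatches integer matrix of mismatched positions.
#' @slot alignedPositions integer matrix of pairwise-aligned positions.
#'
#' @seealso [identityMatrix()], [ampliconMatrix()], [renderIdentityTable()]
#' @export
setClass("IdentityMatrix",
  representation(
    identity = "matrix",
    mismatches = "matrix",
    alignedPositions = "matrix"
  )
)

setValidity("IdentityMatrix", function(object) {
  m <- object@identity
  msg <- character()
  if (!isSymmetric(unname(m))) msg <- c(msg, "identity matrix must be symmetric")
  if (any(diag(m) != 1)) msg <- c(msg, "diagonal identity must be 1")
  if (any(diag(object@mismatches) != 0)) {
    msg <- c(msg, "diagonal mismatches must be 0")
  }
  if (any(m < 0 | m > 1)) msg <- c(msg, "identities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn IdentityMatrix pairwise identity fractions
#' @param x,object an `IdentityMatrix`
#' @export
setGeneric("identities", function(x) standardGeneric("identities"))

#' @export
setMethod("identities", "IdentityMatrix", function(x) x@identity)

#' @describeIn IdentityMatrix pairwise mismatch counts
#' @export
setGeneric("mismatchCounts", function(x) standardGeneric("mismatchCounts"))

#' @export
setMethod("mismatchCounts", "IdentityMatrix", function(x) x@mismatches)

#' @describeIn IdentityMatrix pairwise aligned-position counts
#' @export
setGeneric("alignedPositions", function(x) standardGeneric("alignedPositions"))

#' @export
setMethod("alignedPositions", "IdentityMatrix", function(x) x@alignedPositions)

setMethod("show", "IdentityMatrix", function(object) {
  n <- nrow(object@identity)
  cat("IdentityMatrix over", n, "sequences\n")
  off <- object@identity[upper.tri(object@identity)]
  if (length(off)) {
    cat(sprintf("  identity range: %.3f - %.3f\n", min(off), max(off)))
  }
})

#' Partial genomes accepted by the domain rule
#'
#' Result of [classifyPartialGenomes()]: the contigs accepted as RNA
#' bacteriophage partial genomes (length above the cutoff and at least one
#' phage-specific domain hit), together with their ORFs, domain hits, and
#' the paper-style summary tallies.
#'
#' @slot contigs [Biostrings::DNAStringSet] of accepted contigs.
#' @slot orfs data.frame of ORFs on the accepted contigs (see [findOrfs()]).
#' @slot domainHits data.frame of domain hits (see [scanDomains()]).
#' @slot summary list with elements `n_partial_genomes`, `n_with_rdrp`,
#'   `n_with_maturation`, `n_with_both`.
#'
#' @export
setClass("PartialGenomeSet",
  representation(
    contigs = "DNAStringSet",
    orfs = "data.frame",
    domainHits = "data.frame",
    summary = "list"
  )
)

setValidity("PartialGenomeSet", function(object) {
  s <- object@summary
  msg <- character()
  if (length(s) &&
      s$n_with_both > min(s$n_with_rdrp, s$n_with_maturation)) {
    msg <- c(msg, "n_with_both cannot exceed either single-domain tally")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PartialGenomeSet accepted contigs
#' @param x,object a `PartialGenomeSet`
#' @export
setGeneric("partialGenomes", function(x) standardGeneric("partialGenomes"))

#' @export
setMethod("partialGenomes", "PartialGenomeSet", function(x) x@contigs)

#' @describeIn PartialGenomeSet ORF table
#' @export
setGeneric("orfTable", function(x) standardGeneric("orfTable"))

#' @export
setMethod("orfTable", "PartialGenomeSet", function(x) x@orfs)

#' @describeIn PartialGenomeSet domain hit table
#' @export
setGeneric("domainHits", function(x) standardGeneric("domainHits"))

#' @export
setMethod("domainHits", "PartialGenomeSet", function(x) x@domainHits)

#' @describeIn PartialGenomeSet summary tallies
#' @export
setGeneric("genomeSummary", function(x) standardGeneric("genomeSummary"))

#' @export
setMethod("genomeSummary", "PartialGenomeSet", function(x) x@summary)

setMethod("show", "PartialGenomeSet", function(object) {
  s <- object@summary
  cat("PartialGenomeSet\n")
  cat("  partial genomes:", s$n_partial_genomes, "\n")
  cat("  with RdRp:      ", s$n_with_rdrp, "\n")
  cat("  with maturation:", s$n_with_maturation, "\n")
  cat("  with both:      ", s$n_with_both, "\n")
})

#' Phylotype-by-specimen presence/absence matrix
#'
#' Boolean detection grid built by [buildPresenceMatrix()]; a cell is `TRUE`
#' iff at least one qualifying detection links that phylotype and specimen.
#' Specimen metadata (animal, site, time point) ride along for prevalence
#' and persistence summaries.
#'
#' @slot calls logical matrix, phylotypes in rows, specimens in columns, both
#'   in deterministic (sorted) order.
#' @slot specimenData data.frame of per-specimen metadata (`specimen`,
#'   `animal`, `site`, `time_point`), or NULL.
#'
#' @export
setClass("PresenceMatrix",
  representation(
    calls = "matrix",
    specimenData = "data.frameOrNULL"
  )
)

setValidity("PresenceMatrix", function(object) {
  if (!is.logical(object@calls)) return("calls must be a logical matrix")
  TRUE
})

#' @describeIn PresenceMatrix the logical detection grid
#' @param x,object a `PresenceMatrix`
#' @export
setGeneric("presenceCalls", function(x) standardGeneric("presenceCalls"))

#' @export
setMethod("presenceCalls", "PresenceMatrix", function(x) x@calls)

#' @describeIn PresenceMatrix specimen metadata
#' @export
setGeneric("specimenData", function(x) standardGeneric("specimenData"))

#' @export
setMethod("specimenData", "PresenceMatrix", function(x) x@specimenData)

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@calls), "phylotypes x",
      ncol(object@calls), "specimens;", sum(object@calls),
      "positive cells\n")
})
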