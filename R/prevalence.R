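# Presence/absence matrices, prevalence, persistence, and geographic
# partition checks.

.check_detections <- function(detections) {
  need <- c("specimen", "phylotype")
  miss <- setdiff(need, names(detections))
  if (length(miss)) {
    .stopf("detections table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  for (col in c("animal", "site", "time_point", "evidence")) {
    if (is.null(detections[[col]])) detections[[col]] <- NA_character_
  }
  if (is.null(detections$n_reads)) detections$n_reads <- NA_integer_
  meta <- detections$evidence %in% "metagenomic"
  if (any(meta & (is.na(detections$n_reads) | detections$n_reads < 1L))) {
    .stopf("metagenomic detections require n_reads >= 1")
  }
  detections
}

#' Build a phylotype-by-specimen presence/absence matrix
#'
#' A cell is `TRUE` iff at least one qualifying detection links the
#' phylotype and specimen ("at least one sequence"); for metagenomic
#' evidence a minimal read count can be required. Rows and columns are in
#' deterministic sorted order. When specimen metadata are supplied, every
#' specimen appears as a column even without detections, and detections
#' referencing unknown specimens are an error listing the offenders.
#'
#' @param detections data.frame with columns `specimen`, `phylotype` and
#'   optionally `animal`, `site`, `time_point`, `evidence`
#'   (`"metagenomic"`/`"rtpcr"`), `n_reads`.
#' @param specimens optional metadata data.frame (`specimen`, `animal`,
#'   `site`, `time_point`).
#' @param minReads minimal reads for a metagenomic detection (default 1).
#' @param evidence if non-`NULL`, restrict to this evidence type.
#' @return a [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(detections, specimens = NULL, minReads = 1L,
                                evidence = NULL) {
  detections <- .check_detections(detections)
  if (!is.null(evidence)) {
    detections <- detections[detections$evidence %in% evidence, , drop = FALSE]
  }
  meta <- detections$evidence %in% "metagenomic"
  detections <- detections[!meta | detections$n_reads >= minReads, ,
                           drop = FALSE]
  if (!is.null(specimens)) {
    unknown <- setdiff(detections$specimen, specimens$specimen)
    if (length(unknown)) {
      .stopf("detections reference unknown specimen(s): %s",
             paste(sort(unknown), collapse = ", "))
    }
    spec_ids <- sort(unique(specimens$specimen))
  } else {
    spec_ids <- sort(unique(detections$specimen))
  }
  phylos <- sort(unique(detections$phylotype))
  calls <- matrix(FALSE, length(phylos), length(spec_ids),
                  dimnames = list(phylos, spec_ids))
  if (nrow(detections)) {
    calls[cbind(match(detections$phylotype, phylos),
                match(detections$specimen, spec_ids))] <- TRUE
  }
  sd <- NULL
  if (!is.null(specimens)) {
    sd <- specimens[match(spec_ids, specimens$specimen), , drop = FALSE]
    rownames(sd) <- NULL
  }
  methods::new("PresenceMatrix", calls = calls, specimenData = sd)
}

#' Prevalence summary of a presence matrix
#'
#' Column-wise counts: specimens positive for at least one and at least two
#' phylotypes, plus per-phylotype specimen counts.
#'
#' @param m a [PresenceMatrix-class].
#' @return list with `n_specimens`, `n_specimens_ge1`, `n_specimens_ge2`,
#'   `per_phylotype` (named integer vector).
#' @export
summarizePrevalence <- function(m) {
  calls <- presenceCalls(m)
  if (!ncol(calls)) .stopf("presence matrix has no specimens")
  per_spec <- colSums(calls)
  list(n_specimens = ncol(calls),
       n_specimens_ge1 = sum(per_spec >= 1L),
       n_specimens_ge2 = sum(per_spec >= 2L),
       per_phylotype = setNames(as.integer(rowSums(calls)),
                                rownames(calls)))
}

#' Temporal persistence of a phylotype
#'
#' Groups detections of one phylotype by animal and counts animals positive
#' at one or more time points (`n_animals_positive_any`) and at two or more
#' distinct time points (`n_animals_positive_both_timepoints`). Unknown
#' phylotypes are an error; `NA` time points count as a single
#' (unspecified) time point.
#'
#' @param detections detection table (see [buildPresenceMatrix()]).
#' @param phylotype phylotype to summarise.
#' @return list with `n_animals_positive_any`,
#'   `n_animals_positive_both_timepoints`.
#' @export
persistence <- function(detections, phylotype) {
  detections <- .check_detections(detections)
  if (!phylotype %in% detections$phylotype) {
    .stopf("unknown phylotype '%s'", phylotype)
  }
  d <- detections[detections$phylotype == phylotype, , drop = FALSE]
  tp <- split(as.character(d$time_point), d$animal)
  n_tp <- vapply(tp, function(x) length(unique(x)), integer(1))
  list(n_animals_positive_any = length(n_tp),
       n_animals_positive_both_timepoints = sum(n_tp >= 2L))
}

#' Do amplicon sequences partition by site?
#'
#' Tests whether amplicons cluster perfectly by collection site: `TRUE` iff
#' the minimal within-site identity exceeds the maximal between-site
#' identity. Sites with a single sequence contribute no within-site pairs
#' and are excluded from the within-site mean with a warning.
#'
#' @param im an [IdentityMatrix-class] over the amplicons.
#' @param siteLabels character vector of site labels, one per sequence (in
#'   matrix order).
#' @return list with `distinct_clusters` (logical), `mean_within`,
#'   `mean_between`, `min_within`, `max_between`.
#' @export
sitePartitionCheck <- function(im, siteLabels) {
  idm <- identities(im)
  n <- nrow(idm)
  stopifnot(length(siteLabels) == n)
  if (length(unique(siteLabels)) < 2L) .stopf("need at least 2 sites")
  singles <- names(which(table(siteLabels) == 1L))
  if (length(singles)) {
    .warnf("site(s) with a single sequence excluded from the within-site mean: %s",
           paste(singles, collapse = ", "))
  }
  within <- c(); between <- c()
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (siteLabels[i] == siteLabels[j]) {
        within <- c(within, idm[i, j])
      } else {
        between <- c(between, idm[i, j])
      }
    }
  }
  if (!length(within) || !length(between)) {
    .stopf("need within-site and between-site pairs (>= 2 sites with >= 2 sequences)")
  }
  list(distinct_clusters = min(within) > max(between),
       mean_within = mean(within), mean_between = mean(between),
       min_within = min(within), max_between = max(between))
}

#' Write / read a presence matrix as TSV
#'
#' Lossless round trip: phylotypes in rows, specimens in columns, cells
#' 0/1.
#'
#' @param m a [PresenceMatrix-class].
#' @param path file path.
#' @return `readPresenceMatrix` returns a [PresenceMatrix-class] (without
#'   specimen metadata).
#' @export
writePresenceMatrix <- function(m, path) {
  calls <- presenceCalls(m)
  df <- data.frame(phylotype = rownames(calls),
                   apply(calls, 2L, as.integer, simplify = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePresenceMatrix
#' @export
readPresenceMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  calls <- as.matrix(df) == 1L
  dimnames(calls) <- list(rownames(df), colnames(df))
  methods::new("PresenceMatrix", calls = calls, specimenData = NULL)
}
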