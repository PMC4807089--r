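# Alignment-block trimming, nucleotide distances, neighbour-joining trees
# and bootstrap support.

#' Trimming configuration
#'
#' Parameters of the conserved-block trimming of [trimBlocks()], matching
#' the classic Gblocks parameter semantics: occupancy thresholds for
#' conserved and flank positions, the longest tolerated stretch of
#' contiguous nonconserved positions, the minimal block length, and the gap
#' policy. When the occupancy thresholds are `NULL` they default to
#' `floor(n/2) + 1` (conserved) and `ceiling(0.85 n)` (flank) for `n`
#' sequences.
#'
#' @param minSeqsConserved minimal identical-residue count for a conserved
#'   position.
#' @param minSeqsFlank minimal identical-residue count for a flank position
#'   (must be >= `minSeqsConserved`).
#' @param maxContigNonconserved maximal run of contiguous nonconserved
#'   positions (default 20).
#' @param minBlockLen minimal block length (default 4).
#' @param gapPolicy `"all"` (gap columns eligible, default), `"half"`, or
#'   `"none"`.
#' @return a validated list of class `trim_config`.
#' @export
trimConfig <- function(minSeqsConserved = NULL, minSeqsFlank = NULL,
                       maxContigNonconserved = 20L, minBlockLen = 4L,
                       gapPolicy = c("all", "half", "none")) {
  gapPolicy <- match.arg(gapPolicy)
  structure(list(min_seqs_conserved = minSeqsConserved,
                 min_seqs_flank = minSeqsFlank,
                 max_contig_nonconserved = as.integer(maxContigNonconserved),
                 min_block_len = as.integer(minBlockLen),
                 gap_policy = gapPolicy),
            class = "trim_config")
}

.aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else if (is(aln, "XStringSet")) {
    m <- as.matrix(aln)
  } else {
    s <- .as_char_seqs(aln)
    if (length(unique(nchar(s))) != 1L) {
      .stopf("ragged alignment: sequence lengths differ")
    }
    m <- do.call(rbind, strsplit(toupper(s), ""))
    rownames(m) <- names(s)
  }
  m
}

#' Trim noninformative alignment blocks
#'
#' Gblocks-style conserved-block selection: each column is classified by
#' the occupancy of its most frequent residue (gaps never count as the
#' conserved residue) as nonconserved (`< minSeqsConserved`), conserved, or
#' highly conserved (`>= minSeqsFlank`); runs of contiguous nonconserved
#' columns longer than `maxContigNonconserved` are rejected; remaining
#' blocks are trimmed inwards until they begin and end with a highly
#' conserved (flank) position; blocks shorter than `minBlockLen` are
#' dropped. With `gapPolicy = "none"` every column containing a gap is
#' rejected outright; `"half"` rejects columns with gaps in half or more of
#' the sequences; `"all"` (default) leaves gap columns eligible. The
#' parameter semantics -- not bit-compatibility with the original binary --
#' are the contract.
#'
#' @param aln aligned sequences (XStringSet, character vector, or character
#'   matrix); all rows must have equal length.
#' @param cfg a [trimConfig()].
#' @return list with `alignment` (character matrix of kept columns) and
#'   `kept_columns` (strictly increasing original column indices).
#' @export
trimBlocks <- function(aln, cfg = trimConfig()) {
  m <- .aln_matrix(aln)
  n <- nrow(m); L <- ncol(m)
  cons_t <- cfg$min_seqs_conserved
  flank_t <- cfg$min_seqs_flank
  if (is.null(cons_t)) cons_t <- floor(n / 2) + 1L
  if (is.null(flank_t)) flank_t <- ceiling(0.85 * n)
  if (flank_t < cons_t) .stopf("minSeqsFlank must be >= minSeqsConserved")
  if (n < cons_t) .stopf("fewer sequences (%d) than minSeqsConserved (%d)",
                         n, cons_t)
  gapish <- m %in% c("-", ".")
  dim(gapish) <- dim(m)
  occ <- integer(L)
  gap_n <- integer(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    g <- gapish[, j]
    gap_n[j] <- sum(g)
    occ[j] <- if (all(g)) 0L else max(table(col[!g]))
  }
  eligible <- rep(TRUE, L)
  if (cfg$gap_policy == "none") eligible <- gap_n == 0L
  if (cfg$gap_policy == "half") eligible <- gap_n < n / 2
  class_of <- ifelse(!eligible | occ < cons_t, 0L,
                     ifelse(occ >= flank_t, 2L, 1L))
  keep <- rep(TRUE, L)
  # reject long nonconserved stretches (and all ineligible columns)
  r <- rle(class_of == 0L)
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] > cfg$max_contig_nonconserved) {
      keep[pos[i]:(pos[i + 1L] - 1L)] <- FALSE
    }
  }
  keep[!eligible] <- FALSE
  # blocks between rejected stretches, trimmed to flank positions
  kept_cols <- integer(0)
  r2 <- rle(keep)
  pos2 <- cumsum(c(1L, r2$lengths))
  for (i in seq_along(r2$values)) {
    if (!r2$values[i]) next
    a <- pos2[i]; b <- pos2[i + 1L] - 1L
    while (a <= b && class_of[a] != 2L) a <- a + 1L
    while (b >= a && class_of[b] != 2L) b <- b - 1L
    if (b - a + 1L >= cfg$min_block_len) kept_cols <- c(kept_cols, a:b)
  }
  if (!length(kept_cols)) {
    .warnf("no alignment block satisfies the trimming parameters")
    return(list(alignment = m[, 0, drop = FALSE], kept_columns = integer(0)))
  }
  list(alignment = m[, kept_cols, drop = FALSE], kept_columns = kept_cols)
}

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

#' Kimura 2-parameter distance
#'
#' For an aligned nucleotide pair, `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`
#' with `P` the transition and `Q` the transversion fraction over sites
#' where both sequences have an unambiguous base (gaps and ambiguities
#' excluded pairwise). Saturated pairs (where the logarithm's argument is
#' not positive) are an error.
#'
#' @param a,b equal-length aligned nucleotide sequences.
#' @return the K2P distance (numeric).
#' @export
k2pDistance <- function(a, b) {
  va <- strsplit(toupper(as.character(a)), "")[[1]]
  vb <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(va) != length(vb)) .stopf("sequences must be aligned (equal length)")
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  va <- va[ok]; vb <- vb[ok]
  if (!length(va)) .stopf("no comparable sites")
  diff <- va != vb
  ts <- diff & ((va %in% .PURINES & vb %in% .PURINES) |
                (va %in% .PYRIMIDINES & vb %in% .PYRIMIDINES))
  P <- sum(ts) / length(va)
  Q <- sum(diff & !ts) / length(va)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    .stopf("K2P distance saturated (P = %.3f, Q = %.3f)", P, Q)
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param aln aligned nucleotide sequences.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
k2pMatrix <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- k2pDistance(paste(m[i, ], collapse = ""),
                                          paste(m[j, ], collapse = ""))
      }
    }
  }
  d
}

# pairwise p-distance matrix (fraction differing over comparable sites),
# used for amino-acid alignments
.pdist_matrix <- function(m, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  bad <- if (alphabet == "nt") c("-", ".", "N") else c("-", ".", "X", "*")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- !(m[i, ] %in% bad) & !(m[j, ] %in% bad)
        d[i, j] <- d[j, i] <-
          if (any(ok)) mean(m[i, ok] != m[j, ok]) else NA_real_
      }
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining on a symmetric distance matrix (via
#' [ape::nj()]); negative branch lengths are clamped to zero. Fewer than
#' three taxa are an error.
#'
#' @param d symmetric numeric distance matrix (or `dist`).
#' @return an unrooted [ape::phylo] tree.
#' @export
njTree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) .stopf("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `nReps` times, rebuilds the tree per replicate, and
#' annotates the full-data tree's internal nodes with bipartition support
#' as percentages in [0, 100]. Replicates whose distances are incomputable
#' (e.g. K2P saturation) are dropped with a warning and support is scaled
#' to the successful replicates. `nReps = 0` returns the tree without
#' support annotations. The same seed always gives the same supports.
#'
#' @param aln aligned sequences (nucleotide for `distance = "k2p"`, any for
#'   `"p"`).
#' @param nReps bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param distance `"k2p"` or `"p"` (p-distance).
#' @return an [ape::phylo] tree; `node.label` holds support percentages.
#' @export
bootstrapSupport <- function(aln, nReps = 100L, seed = 1L,
                             distance = c("k2p", "p")) {
  distance <- match.arg(distance)
  m <- .aln_matrix(aln)
  distfun <- function(mm) {
    if (distance == "k2p") k2pMatrix(mm) else .pdist_matrix(mm)
  }
  full <- njTree(distfun(m))
  if (nReps == 0L) return(full)
  reps <- .with_seed(seed, {
    lapply(seq_len(nReps), function(i) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tryCatch(njTree(distfun(m[, cols, drop = FALSE])),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (!all(ok)) {
    .warnf("%d of %d bootstrap replicates failed and were dropped",
           sum(!ok), nReps)
  }
  reps <- reps[ok]
  if (!length(reps)) .stopf("all bootstrap replicates failed")
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- round(100 * counts / length(reps), 1)
  full
}
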