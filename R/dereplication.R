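# Pairwise identity, phylotype dereplication, species delimitation and
# nomenclature.

#' Global alignment identity (p-distance convention)
#'
#' Needleman-Wunsch global alignment with affine gaps (nucleotide:
#' match +2 / mismatch -3, gap open 5 extend 2; amino acid: BLOSUM62, gap
#' open 11 extend 1; a gap of length L costs open + L * extend). Identity is
#' computed with pairwise gap deletion, the p-distance convention: the
#' denominator counts only columns where both sequences place an unambiguous
#' residue, identity is the fraction of those columns that match, and
#' mismatches the remainder. Gap columns count neither as matches nor
#' mismatches.
#'
#' In addition to the gap-deleted statistics, `span_identity` reports a
#' BLAST-flavoured identity over the alignment span: identical columns
#' divided by all columns between the first and last aligned residue pair,
#' so internal gaps count against identity while terminal overhangs (e.g.
#' a truncated gene against a complete one) do not.
#'
#' @param a,b sequences (character or XString).
#' @param alphabet `"nt"` or `"aa"`.
#' @return list with `identity`, `mismatches`, `aligned_positions`,
#'   `span_identity`, `span_columns`, `score`.
#' @export
globalAlignIdentity <- function(a, b, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  a <- as.character(a); b <- as.character(b)
  if (!nchar(a) || !nchar(b)) .stopf("cannot align an empty sequence")
  if (alphabet == "nt") {
    sm <- .nt_matrix()
    ca <- .encode_nt(a); cb <- .encode_nt(b)
    amb_a <- ca == 4L; amb_b <- cb == 4L
    go <- 5L; ge <- 2L
  } else {
    sm <- .blosum62()
    ca <- .encode_aa(a); cb <- .encode_aa(b)
    xi <- match("X", .aa_alphabet()) - 1L
    amb_a <- ca == xi; amb_b <- cb == xi
    go <- 11L; ge <- 1L
  }
  r <- cpp_global_align(ca, cb, sm, go, ge, amb_a, amb_b)
  aligned <- r$aligned
  list(identity = if (aligned > 0) r$identical / aligned else NA_real_,
       mismatches = as.integer(aligned - r$identical),
       aligned_positions = as.integer(aligned),
       span_identity = if (r$span_columns > 0) r$identical / r$span_columns
                       else NA_real_,
       span_columns = as.integer(r$span_columns),
       score = r$score)
}

#' Pairwise identity matrix over a sequence set
#'
#' Runs [globalAlignIdentity()] over every pair and assembles the symmetric
#' identity / mismatch / aligned-position matrices.
#'
#' @param seqs named sequences (XStringSet or character vector).
#' @param alphabet `"nt"` or `"aa"`.
#' @return an [IdentityMatrix-class].
#' @export
identityMatrix <- function(seqs, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  s <- .as_char_seqs(seqs)
  n <- length(s)
  nm <- names(s)
  idm <- matrix(1, n, n, dimnames = list(nm, nm))
  mm <- matrix(0L, n, n, dimnames = list(nm, nm))
  ap <- matrix(0L, n, n, dimnames = list(nm, nm))
  diag(ap) <- nchar(s)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        r <- globalAlignIdentity(s[i], s[j], alphabet)
        idm[i, j] <- idm[j, i] <- r$identity
        mm[i, j] <- mm[j, i] <- r$mismatches
        ap[i, j] <- ap[j, i] <- r$aligned_positions
      }
    }
  }
  methods::new("IdentityMatrix", identity = idm, mismatches = mm,
               alignedPositions = ap)
}

# single-linkage components of a thresholded identity graph
.identity_components <- function(idm, threshold, strict) {
  n <- nrow(idm)
  adj <- if (strict) idm > threshold else idm >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Dereplicate partial genomes into phylotypes
#'
#' Applies the phylotype rule: partial genomes sharing strictly more than
#' `threshold` (default 0.70) nucleotide identity in the RdRp gene or the
#' maturation gene belong to one phylotype; the relation is closed
#' transitively (single linkage), and each phylotype's representative is
#' its longest member (ties: lexicographically smallest id). Genomes
#' lacking both genes are excluded with a warning.
#'
#' By default the identity compared against the threshold is the alignment-
#' span identity of [globalAlignIdentity()] (internal gaps count, terminal
#' overhangs do not), matching the behaviour of the BLASTn identities the
#' rule was formulated for; `identity = "pdist"` uses the gap-deleted
#' p-distance identity instead, which can be substantially inflated when a
#' truncated gene meets a complete one.
#'
#' @param genomes data.frame with columns `id`, `length`, and gene sequence
#'   columns `rdrp` and/or `maturation` (`NA` when absent).
#' @param gene which gene(s) link genomes: `"either"` (default), `"rdrp"`,
#'   or `"maturation"`.
#' @param threshold identity threshold (strict `>`; default 0.70).
#' @param identity identity flavour: `"span"` (default) or `"pdist"`.
#' @return data.frame with one row per phylotype: `phylotype`, `n_members`,
#'   `members` (comma-separated ids), `representative`,
#'   `representative_length`.
#' @export
clusterPhylotypes <- function(genomes, gene = c("either", "rdrp", "maturation"),
                              threshold = 0.70,
                              identity = c("span", "pdist")) {
  gene <- match.arg(gene)
  identity <- match.arg(identity)
  id_field <- if (identity == "span") "span_identity" else "identity"
  use <- if (gene == "either") c("rdrp", "maturation") else gene
  for (g in use) if (is.null(genomes[[g]])) genomes[[g]] <- NA_character_
  has_any <- Reduce(`|`, lapply(use, function(g) !is.na(genomes[[g]])))
  if (any(!has_any)) {
    .warnf("excluding %d genome(s) lacking the %s gene(s): %s",
           sum(!has_any), paste(use, collapse = "/"),
           paste(genomes$id[!has_any], collapse = ", "))
    genomes <- genomes[has_any, , drop = FALSE]
  }
  n <- nrow(genomes)
  if (!n) .stopf("no genomes carry the required gene(s)")
  adj <- matrix(FALSE, n, n)
  for (g in use) {
    idx <- which(!is.na(genomes[[g]]))
    if (length(idx) < 2L) next
    for (ii in 1:(length(idx) - 1L)) {
      for (jj in (ii + 1L):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        if (adj[i, j]) next
        r <- globalAlignIdentity(genomes[[g]][i], genomes[[g]][j], "nt")
        if (!is.na(r[[id_field]]) && r[[id_field]] > threshold) {
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  out <- lapply(sort(unique(memb)), function(cl) {
    rows <- genomes[memb == cl, , drop = FALSE]
    rows <- rows[order(-rows$length, rows$id), , drop = FALSE]
    data.frame(n_members = nrow(rows),
               members = paste(sort(rows$id), collapse = ","),
               representative = rows$id[1],
               representative_length = rows$length[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # stable, content-derived order and labels
  out <- out[order(out$members), , drop = FALSE]
  out <- cbind(phylotype = sprintf("PT%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Count species at an amino-acid identity cutoff
#'
#' Number of single-linkage clusters when sequences sharing at least
#' `cutoff` percent identity (non-strict, per the species rule) are linked.
#'
#' @param im an [IdentityMatrix-class] (typically over RdRp proteins).
#' @param cutoff identity cutoff in percent (e.g. 60).
#' @return integer cluster count.
#' @export
countSpecies <- function(im, cutoff) {
  memb <- .identity_components(identities(im), cutoff / 100, strict = FALSE)
  length(unique(memb))
}

#' Species counts across identity cutoffs
#'
#' Tabulates [countSpecies()] over a vector of amino-acid identity cutoffs.
#' Counts are necessarily non-decreasing in the cutoff (raising the cutoff
#' can only split clusters); this invariant is checked.
#'
#' @param im an [IdentityMatrix-class].
#' @param cutoffs identity cutoffs in percent (default `c(70, 60, 50, 40)`).
#' @return data.frame with columns `cutoff`, `n_species`.
#' @export
speciesTable <- function(im, cutoffs = c(70, 60, 50, 40)) {
  counts <- vapply(cutoffs, function(co) countSpecies(im, co), integer(1))
  ord <- order(cutoffs)
  if (is.unsorted(counts[ord])) {
    .stopf("species counts must be non-decreasing in the cutoff")
  }
  data.frame(cutoff = cutoffs, n_species = counts)
}

#' Amplicon identity/mismatch matrix
#'
#' Pairwise identity and mismatch counts over a set of amplicon sequences,
#' from the same global alignments, for rendering as a combined table
#' (identities above the diagonal, mismatch counts below).
#'
#' @param amplicons named nucleotide sequences (>= 2).
#' @return an [IdentityMatrix-class].
#' @export
ampliconMatrix <- function(amplicons) {
  s <- .as_char_seqs(amplicons)
  if (length(s) < 2L) .stopf("need at least 2 amplicons")
  identityMatrix(s, "nt")
}

#' Render an identity matrix as a combined top/bottom table
#'
#' Upper triangle: pairwise identity to `digits` decimals; lower triangle:
#' integer mismatch counts; empty diagonal.
#'
#' @param im an [IdentityMatrix-class].
#' @param digits decimals for identities (default 2).
#' @return a character data.frame.
#' @export
renderIdentityTable <- function(im, digits = 2L) {
  idm <- identities(im); mm <- mismatchCounts(im)
  n <- nrow(idm)
  out <- matrix("", n, n, dimnames = dimnames(idm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) out[i, j] <- formatC(idm[i, j], format = "f", digits = digits)
      if (i > j) out[i, j] <- as.character(mm[i, j])
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

.NICHE_CODES <- c("IN", "VE", "SE", "SO", "MS", "MM", "OC")

#' Novel phage name in the discovery nomenclature
#'
#' One letter for the specimen source (A = animal, E = environmental), a
#' two-letter ecological niche code (IN invertebrate, VE vertebrate, SE
#' sewage, SO soil, MS microbial sediment, MM microbial mat, OC ocean), and
#' a zero-padded three-digit index: e.g. `assignName("animal", "VE", 0)` is
#' `"AVE000"`.
#'
#' @param source `"animal"` or `"environmental"`.
#' @param niche one of the two-letter niche codes.
#' @param index integer in 0..999.
#' @return character name.
#' @export
assignName <- function(source = c("animal", "environmental"), niche, index) {
  source <- match.arg(source)
  if (!niche %in% .NICHE_CODES) {
    .stopf("unknown niche '%s' (expected one of %s)", niche,
           paste(.NICHE_CODES, collapse = ", "))
  }
  if (index < 0 || index > 999) .stopf("index must lie in 0..999, got %d", index)
  sprintf("%s%s%03d", if (source == "animal") "A" else "E", niche,
          as.integer(index))
}
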