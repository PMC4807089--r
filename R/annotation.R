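# ORF prediction, ORF overlap measurement, and partial-genome
# classification. Domain scanning lives in motif-models.R.

#' Predict ORFs in all six frames
#'
#' Reports maximal open reading frames on both strands: within each frame,
#' every stop codon closes the segment that began after the previous stop,
#' and the segment's ORF runs from its first allowed start codon to the
#' stop (inclusive). Segments that touch a contig edge are reported as
#' partial ORFs: a segment with no upstream stop yields a 5'-partial ORF
#' spanning the whole segment (no start codon required), and a segment that
#' runs off the end without a stop yields a 3'-partial ORF from its first
#' start. Coordinates are 0-based half-open on the forward strand; `frame`
#' follows the `+1..-3` convention; proteins exclude the stop.
#'
#' @param contig nucleotide sequence (character or [Biostrings::DNAString]).
#' @param minAa minimal protein length in amino acids (default 50).
#' @param startCodons allowed start codons (bacterial usage by default).
#' @param contigId identifier copied into the result.
#' @return data.frame with columns `contig`, `orf_id`, `start`, `end`,
#'   `strand`, `frame`, `aa_len`, `partial5`, `partial3`, `protein`.
#' @export
findOrfs <- function(contig, minAa = 50L,
                     startCodons = c("ATG", "GTG", "TTG"),
                     contigId = "contig") {
  s <- toupper(as.character(contig))
  L <- nchar(s)
  if (L < 3L) .stopf("contig shorter than one codon")
  gc <- .genetic_code()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rows <- list()
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else rc
    v <- strsplit(str, "")[[1]]
    for (off in 0:2) {
      n_cod <- (L - off) %/% 3L
      if (n_cod < 1L) next
      i1 <- off + 1L + 3L * (seq_len(n_cod) - 1L)
      cods <- paste0(v[i1], v[i1 + 1L], v[i1 + 2L])
      aa <- unname(gc[cods])
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      is_start <- cods %in% startCodons
      stops <- which(is_stop)
      seg_start <- c(1L, stops + 1L)
      seg_stop <- c(stops, NA_integer_)  # NA: runs off the 3' end
      emit <- function(orf_cod, partial5, partial3) {
        prot_cod <- if (partial3) orf_cod else orf_cod[-length(orf_cod)]
        if (length(prot_cod) < minAa) return(NULL)
        prot <- paste(aa[prot_cod], collapse = "")
        c0 <- off + 3L * (orf_cod[1] - 1L)            # 0-based on `str`
        c1 <- off + 3L * orf_cod[length(orf_cod)]      # half-open
        if (strand == "+") {
          start <- c0; end <- c1
        } else {
          start <- L - c1; end <- L - c0
        }
        data.frame(
          contig = contigId, start = start, end = end, strand = strand,
          frame = paste0(strand, off + 1L), aa_len = length(prot_cod),
          partial5 = partial5, partial3 = partial3, protein = prot,
          stringsAsFactors = FALSE)
      }
      for (g in seq_along(seg_start)) {
        a <- seg_start[g]
        z <- seg_stop[g]
        b <- if (is.na(z)) n_cod else z
        if (b < a) next
        partial3 <- is.na(z)
        start_lim <- if (partial3) b else b - 1L
        st <- if (start_lim >= a) which(is_start[a:start_lim]) else integer(0)
        # segments touching the contig edge: the reading frame may run in
        # from a truncated gene, so report the edge-anchored maximal ORF as
        # 5'-partial; a start codon inside the segment additionally yields
        # the usual start-to-stop ORF (unless the two coincide)
        if (a == 1L && (!length(st) || st[1] > 1L)) {
          r <- emit(a:b, TRUE, partial3)
          if (!is.null(r)) rows[[length(rows) + 1L]] <- r
        }
        if (length(st)) {
          r <- emit((a + st[1] - 1L):b, FALSE, partial3)
          if (!is.null(r)) rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(), orf_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), frame = character(),
                      aa_len = integer(), partial5 = logical(),
                      partial3 = logical(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  out <- cbind(contig = out$contig,
               orf_id = sprintf("%s_orf%02d", contigId, seq_len(nrow(out))),
               out[, setdiff(names(out), "contig"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Coordinate overlap between two ORFs
#'
#' Length, in nucleotides, of the intersection of the two ORFs' coordinate
#' intervals on their shared contig; 0 when disjoint. ORFs on different
#' contigs are an error.
#'
#' @param a,b single ORF rows (data.frame rows or lists with `contig`,
#'   `start`, `end`).
#' @return integer nucleotide overlap.
#' @export
measureOrfOverlap <- function(a, b) {
  ca <- if (!is.null(a[["contig"]])) a[["contig"]] else NA
  cb <- if (!is.null(b[["contig"]])) b[["contig"]] else NA
  if (!is.na(ca) && !is.na(cb) && !identical(as.character(ca), as.character(cb))) {
    .stopf("ORFs lie on different contigs ('%s' vs '%s')", ca, cb)
  }
  max(0L, as.integer(min(a[["end"]], b[["end"]]) -
                     max(a[["start"]], b[["start"]])))
}

#' Scan all ORFs of a contig set for phage domains
#'
#' Convenience wrapper running [scanDomains()] over every ORF in an ORF
#' table (edge-partial ORFs included: real partial genomes truncate genes).
#'
#' @param orfs ORF table from [findOrfs()] (rows from multiple contigs may
#'   be concatenated).
#' @param models passed to [scanDomains()].
#' @return data.frame of domain hits with a `contig` column joined in.
#' @export
scanOrfDomains <- function(orfs, models = motifModels()) {
  hits <- lapply(seq_len(nrow(orfs)), function(i) {
    h <- scanDomains(orfs$protein[i], models, orfId = orfs$orf_id[i])
    if (nrow(h)) h$contig <- orfs$contig[i]
    h
  })
  hits <- hits[vapply(hits, nrow, integer(1)) > 0L]
  if (!length(hits)) {
    return(data.frame(orf = character(), domain = character(),
                      score = integer(), threshold = integer(),
                      motif_coverage = character(), protein_start = integer(),
                      protein_end = integer(), contig = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Classify contigs as RNA bacteriophage partial genomes
#'
#' Applies the partial-genome definition: a contig is accepted when it is
#' strictly longer than `minLen` nucleotides and at least one of its
#' translated frames carries a recognisable phage-specific domain. Summary
#' tallies count accepted contigs carrying an RdRp domain, a maturation
#' domain, and both.
#'
#' @param contigs [Biostrings::DNAStringSet].
#' @param orfs ORF table over those contigs ([findOrfs()]).
#' @param hits domain hit table ([scanOrfDomains()]).
#' @param minLen length cutoff (default 750, strict).
#' @return a [PartialGenomeSet-class].
#' @export
classifyPartialGenomes <- function(contigs, orfs, hits, minLen = 750L) {
  long_enough <- names(contigs)[Biostrings::width(contigs) > minLen]
  with_hit <- unique(hits$contig)
  accepted <- intersect(long_enough, with_hit)
  acc_hits <- hits[hits$contig %in% accepted, , drop = FALSE]
  has_dom <- function(doms) {
    unique(acc_hits$contig[acc_hits$domain %in% doms])
  }
  rdrp <- has_dom(c("rdrp_ss", "rdrp_ds"))
  mat <- has_dom("maturation")
  methods::new("PartialGenomeSet",
               contigs = contigs[accepted],
               orfs = orfs[orfs$contig %in% accepted, , drop = FALSE],
               domainHits = acc_hits,
               summary = list(n_partial_genomes = length(accepted),
                              n_with_rdrp = length(rdrp),
                              n_with_maturation = length(mat),
                              n_with_both = length(intersect(rdrp, mat))))
}
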