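# Toy greedy overlap assembly and the contig length filter.

#' Greedy overlap assembly
#'
#' Assembles reads by greedy suffix-prefix merging with consensus voting: a
#' read joins a growing contig when it shares a k-mer with it and overlaps
#' by at least `minOverlap` positions (either strand) with a mismatch
#' fraction at most `maxMismatchRate`; among valid candidates the longest
#' overlap wins (containments absorb first), then the longest extension,
#' with ties broken on the lexicographically smallest oriented read
#' sequence. Seeds are processed longest-read first, so the resulting
#' contigs do not depend on input order (only contig names can differ after
#' canonicalisation). Each contig is reported on its canonical strand (the
#' lexicographically smaller of sequence / reverse complement). Reads that
#' merge nowhere emerge as singleton contigs.
#'
#' This is deliberately a small-scale overlap assembler: the surrounding
#' selection rules, not the assembler, are the object of study here.
#'
#' @param reads [Biostrings::DNAStringSet] (or named character vector).
#' @param minOverlap minimal suffix-prefix overlap, nt.
#' @param maxMismatchRate maximal mismatch fraction within an overlap.
#' @param kmer seeding k-mer size; capped at `minOverlap`.
#' @return [Biostrings::DNAStringSet] of contigs named `contig_0001` ...,
#'   ordered by decreasing length; metadata column `n_reads` gives the
#'   number of reads per contig, and `attr(, "membership")` maps every read
#'   to its contig.
#' @export
greedyAssemble <- function(reads, minOverlap = 30L, maxMismatchRate = 0.02,
                           kmer = 12L) {
  seqs <- .as_char_seqs(reads)
  if (!length(seqs)) .stopf("no reads to assemble")
  k <- min(as.integer(kmer), as.integer(minOverlap))
  res <- cpp_greedy_assemble(unname(seqs), as.integer(minOverlap),
                             maxMismatchRate, k)
  ord <- order(-nchar(res$contigs), res$contigs)
  contigs <- Biostrings::DNAStringSet(res$contigs[ord])
  names(contigs) <- sprintf("contig_%04d", seq_along(contigs))
  S4Vectors::mcols(contigs)$n_reads <- res$n_reads[ord]
  membership <- data.frame(
    read = names(seqs),
    contig = names(contigs)[match(res$read2contig, ord)],
    stringsAsFactors = FALSE)
  attr(contigs, "membership") <- membership
  contigs
}

#' Contig length filter
#'
#' Retains contigs strictly longer than `minLen` nucleotides (the partial-
#' genome length rule: "greater than 750" is a strict inequality, so a
#' 750-nt contig is dropped).
#'
#' @param contigs [Biostrings::DNAStringSet].
#' @param minLen length cutoff, nt (default 750).
#' @return the filtered [Biostrings::DNAStringSet].
#' @export
filterContigs <- function(contigs, minLen = 750L) {
  contigs[Biostrings::width(contigs) > minLen]
}
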