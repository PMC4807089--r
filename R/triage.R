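# Translated homology triage: six-frame translation, seeded translated
# local search with Karlin-Altschul statistics, and the >= 10-significant-
# reads dataset selection rule.

.FRAME_LABELS <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames: +1..+3 from
#' the forward sequence, -1..-3 from its reverse complement, dropping the
#' 1-2 trailing nucleotides that do not complete a codon. Codons containing
#' N translate to `X`; stop codons are rendered `*`. Sequences shorter than
#' one codon give six empty frames with a warning.
#'
#' @param seq a nucleotide sequence (character, [Biostrings::DNAString]) or
#'   a [Biostrings::DNAStringSet].
#' @return for a single sequence, an [Biostrings::AAStringSet] of length 6
#'   named `+1, +2, +3, -1, -2, -3`; for a set, a list of such objects.
#' @export
sixFrameTranslate <- function(seq) {
  if (is(seq, "DNAStringSet") || (is.character(seq) && length(seq) > 1L)) {
    return(lapply(.as_char_seqs(seq), sixFrameTranslate))
  }
  s <- toupper(as.character(seq))
  L <- nchar(s)
  if (L < 3L) {
    .warnf("sequence shorter than one codon: all frames empty")
    out <- Biostrings::AAStringSet(rep("", 6L))
    names(out) <- .FRAME_LABELS
    return(out)
  }
  fwd <- Biostrings::DNAString(s)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(x, off) {
    w <- (length(x) - off) %/% 3L
    if (w < 1L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, start = off + 1L, width = 3L * w),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  frames <- c(vapply(0:2, function(o) one(fwd, o), character(1)),
              vapply(0:2, function(o) one(rev, o), character(1)))
  out <- Biostrings::AAStringSet(frames)
  names(out) <- .FRAME_LABELS
  out
}

.default_search_params <- function() {
  list(word_size = 3L, word_threshold = 13L, gap_open = 11L, gap_ext = 1L,
       lambda = .KA_LAMBDA, K = .KA_K)
}

# integer-coded six frames for a whole read set, in frame order
.encode_frames <- function(reads) {
  seqs <- .as_char_seqs(reads)
  x <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(x)
  frame_strings <- function(set, off) {
    w <- pmax(0L, (Biostrings::width(set) - off) %/% 3L)
    out <- character(length(set))
    ok <- w >= 1L
    if (any(ok)) {
      sub <- Biostrings::subseq(set[ok], start = off + 1L, width = 3L * w[ok])
      out[ok] <- as.character(Biostrings::translate(
        sub, if.fuzzy.codon = "solve", no.init.codon = TRUE))
    }
    out
  }
  per_frame <- c(lapply(0:2, function(o) frame_strings(x, o)),
                 lapply(0:2, function(o) frame_strings(rc, o)))
  lapply(seq_along(seqs), function(i) {
    lapply(1:6, function(f) .encode_aa(per_frame[[f]][i]))
  })
}

#' Translated local search of reads against protein queries
#'
#' A tBLASTn-like search: every read is translated in six frames and
#' scanned for BLAST-style neighbourhood word seeds (word size 3, word
#' score threshold `word_threshold` under BLOSUM62); seeded frame/query
#' pairs are aligned by full local Gotoh alignment (BLOSUM62, gap open 11,
#' extend 1), and the best HSP per (read, frame, query) is reported with
#' Karlin-Altschul statistics (`lambda` = 0.267, `K` = 0.041, database size
#' = total translated letters across all frames of all reads). Ambiguous
#' translation products (`X`) score as the worst column entry and never
#' seed.
#'
#' @param queries protein queries ([Biostrings::AAStringSet] or named
#'   character vector).
#' @param reads nucleotide reads ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param evalueMax if non-`NULL`, retain only hits with E-value strictly
#'   below this cutoff.
#' @param params search parameters; see `Details`.
#' @return data.frame with columns `read_id`, `query_id`, `frame`
#'   (`"+1".."-3"`), `score` (raw BLOSUM62 units), `bits`, `evalue`, and
#'   0-based half-open aligned intervals `read_start`, `read_end` (on the
#'   translated frame) and `query_start`, `query_end`.
#' @export
translatedSearch <- function(queries, reads, evalueMax = NULL,
                             params = .default_search_params()) {
  qseq <- .as_char_seqs(queries)
  rseq <- .as_char_seqs(reads)
  if (!length(qseq) || !length(rseq)) .stopf("queries and reads must be non-empty")
  qcodes <- lapply(qseq, .encode_aa)
  frames <- .encode_frames(rseq)
  db_letters <- sum(vapply(frames, function(fr)
    sum(lengths(fr)), numeric(1)))
  empty <- data.frame(read_id = character(), query_id = character(),
                      frame = character(), score = integer(),
                      bits = numeric(), evalue = numeric(),
                      read_start = integer(), read_end = integer(),
                      query_start = integer(), query_end = integer(),
                      stringsAsFactors = FALSE)
  if (db_letters == 0) return(empty)
  sm <- .search_matrix()
  lookup <- cpp_word_lookup(qcodes, sm, params$word_threshold)
  hits <- cpp_translated_search(
    frames, qcodes, sm, params$gap_open, params$gap_ext, lookup,
    params$lambda, log(params$K), db_letters,
    if (is.null(evalueMax)) Inf else evalueMax)
  if (!nrow(hits)) return(empty)
  data.frame(read_id = names(rseq)[hits$read],
             query_id = names(qseq)[hits$query],
             frame = .FRAME_LABELS[hits$frame],
             score = hits$score, bits = hits$bits, evalue = hits$evalue,
             read_start = hits$read_start, read_end = hits$read_end,
             query_start = hits$query_start, query_end = hits$query_end,
             stringsAsFactors = FALSE)
}

#' Dataset triage by significant-read count
#'
#' Applies the dataset selection rule: a dataset is selected for assembly
#' when at least `minReads` *distinct* reads have at least one alignment
#' with E-value strictly below `evalueCutoff`. Multiple HSPs from one read
#' count once.
#'
#' @param hits hit table from [translatedSearch()].
#' @param minReads minimal number of significant reads (default 10).
#' @param evalueCutoff significance cutoff (default `1e-4`, strict `<`).
#' @param datasetId identifier copied into the result.
#' @return list with `dataset_id`, `n_significant_reads`, `selected`.
#' @export
triageDataset <- function(hits, minReads = 10L, evalueCutoff = 1e-4,
                          datasetId = "dataset") {
  n <- if (nrow(hits)) length(unique(hits$read_id[hits$evalue < evalueCutoff])) else 0L
  list(dataset_id = datasetId, n_significant_reads = n,
       selected = n >= minReads)
}
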