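# Plain-file input/output: community exports, GFF3, FASTQ, and a minimal
# GenBank flat-file reader for reference / deposited partial-genome records.

#' ORF feature table as GRanges
#'
#' Converts the 0-based half-open internal feature coordinates to the
#' 1-based inclusive convention of GFF3/GenBank-style output.
#'
#' @param features data.frame with `genome` (or `contig`), `start`, `end`,
#'   `strand` and annotation columns.
#' @return a [GenomicRanges::GRanges].
#' @export
featuresToGRanges <- function(features) {
  seqn <- if (!is.null(features$genome)) features$genome else features$contig
  gr <- GenomicRanges::GRanges(
    seqnames = seqn,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  extra <- setdiff(names(features), c("genome", "contig", "start", "end",
                                      "strand"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- features[[col]]
  gr
}

#' Write a synthetic community to a directory
#'
#' Writes `genomes.fasta`, `reads.fasta` (or `reads.fastq` with constant
#' Q30 qualities), `features.gff3` (1-based inclusive), `truth.tsv`, and a
#' `spec.json` echo of the generating parameters.
#'
#' @param community a [PhageCommunity-class].
#' @param dir output directory (created if needed).
#' @param fastq write reads as FASTQ instead of FASTA.
#' @return invisibly, the directory.
#' @export
writeCommunity <- function(community, dir, fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genomes(community),
                              file.path(dir, "genomes.fasta"))
  if (fastq) {
    writeFastq(reads(community), file.path(dir, "reads.fastq"))
  } else {
    Biostrings::writeXStringSet(reads(community),
                                file.path(dir, "reads.fasta"))
  }
  ft <- communityFeatures(community)
  ft$type <- "CDS"
  ft$phase <- 0L
  gr <- featuresToGRanges(ft)
  rtracklayer::export(gr, file.path(dir, "features.gff3"), format = "gff3")
  utils::write.table(readTruth(community), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- community@spec
  spec$orf_aa <- NULL
  jsonlite::write_json(spec, file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write reads as FASTQ with constant Q30 qualities
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
writeFastq <- function(reads, path) {
  q <- vapply(Biostrings::width(reads),
              function(w) paste(rep("?", w), collapse = ""), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(reads), "\n", as.character(reads), "\n+\n", q),
             con)
  invisible(path)
}

.parse_gb_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  partial5 <- grepl("<", loc)
  partial3 <- grepl(">", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, "\\.\\.")[[1]]
  start <- as.integer(parts[1])
  end <- as.integer(if (length(parts) > 1L) parts[2] else parts[1])
  list(start = start, end = end, strand = strand,
       partial5 = partial5, partial3 = partial3)
}

#' Minimal GenBank flat-file reader
#'
#' Parses the subset of the GenBank format needed for annotated reference
#' records and deposited partial genomes: LOCUS name and length,
#' DEFINITION, FEATURES entries (gene/CDS with simple or `complement()`
#' locations and `/gene`, `/product` qualifiers), and the ORIGIN sequence.
#' Feature coordinates are returned 0-based half-open to match the rest of
#' the package.
#'
#' @param path path to a GenBank flat file.
#' @return list with `name`, `definition`, `length`, `features`
#'   (data.frame: `type`, `start`, `end`, `strand`, `partial5`, `partial3`,
#'   `gene`, `product`), `sequence` (character).
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) .stopf("not a GenBank record: no LOCUS line in '%s'", path)
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  name <- toks[2]
  len <- suppressWarnings(as.integer(toks[3]))
  defn <- sub("^DEFINITION\\s+", "", grep("^DEFINITION", lines, value = TRUE)[1])
  f0 <- grep("^FEATURES", lines)
  o0 <- grep("^ORIGIN", lines)
  feats <- list()
  if (length(f0)) {
    end_feat <- if (length(o0)) o0[1] - 1L else length(lines)
    block <- lines[(f0[1] + 1L):end_feat]
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      loc <- .parse_gb_location(cur$loc)
      data.frame(type = cur$type, start = loc$start - 1L, end = loc$end,
                 strand = loc$strand, partial5 = loc$partial5,
                 partial3 = loc$partial3,
                 gene = cur$qual[["gene"]] %||% NA_character_,
                 product = cur$qual[["product"]] %||% NA_character_,
                 stringsAsFactors = FALSE)
    }
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {
        feats[[length(feats) + 1L]] <- flush(cur)
        tk <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(type = tk[1], loc = tk[2], qual = list())
      } else if (!is.null(cur) && grepl("^\\s+/", ln)) {
        q <- sub("^\\s+/", "", ln)
        kv <- strsplit(q, "=", fixed = TRUE)[[1]]
        if (length(kv) == 2L) {
          cur$qual[[kv[1]]] <- gsub("\"", "", kv[2])
        }
      } else if (!is.null(cur) && grepl("^\\s+[^/]", ln) &&
                 !grepl("\\.\\.", cur$loc)) {
        cur$loc <- paste0(cur$loc, trimws(ln))
      }
    }
    feats[[length(feats) + 1L]] <- flush(cur)
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(type = character(), start = integer(), end = integer(),
               strand = character(), partial5 = logical(),
               partial3 = logical(), gene = character(),
               product = character(), stringsAsFactors = FALSE)
  seq <- ""
  if (length(o0)) {
    end_o <- grep("^//", lines)
    end_o <- if (length(end_o)) end_o[1] - 1L else length(lines)
    body <- lines[(o0[1] + 1L):end_o]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  if (is.na(len)) len <- nchar(seq)
  list(name = name, definition = defn, length = len, features = features,
       sequence = seq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
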