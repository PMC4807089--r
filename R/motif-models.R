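# Packaged motif models for phage-specific domain assignment.
#
# The models stand in for the external conserved-domain and structural
# searches of the original workflow: each phage domain (ssRNA RdRp,
# maturation, coat, lysin, dsRNA RdRp, packaging NTPase, peptidoglycan
# hydrolase) is represented by a position-specific profile built from a
# packaged reference protein (a synthetic stand-in set shipped with the
# package -- see inst/extdata/synthetic_reference_proteins.faa), scored with
# BLOSUM62 by best ungapped local segment. The ssRNA RdRp model additionally
# carries the coordinates of the five palm-domain motifs (A-E), so hits can
# report which motifs are covered.

# Motif/block coordinates on each family's consensus member (0-based,
# half-open amino-acid intervals). Must match the packaged FASTA.
.MODEL_DEFS <- list(
  rdrp_ss = list(
    consensus = "synref_rdrp_ss_1",
    motifs = list(A = c(240L, 252L), B = c(285L, 299L), C = c(330L, 340L),
                  D = c(370L, 380L), E = c(405L, 413L))
  ),
  maturation = list(
    consensus = "synref_maturation_1",
    motifs = list(b1 = c(60L, 78L), b2 = c(300L, 318L))
  ),
  coat = list(
    consensus = "synref_coat_1",
    motifs = list(b1 = c(25L, 39L), b2 = c(85L, 99L))
  ),
  lysin = list(consensus = "synref_lysin_1", motifs = list()),
  rdrp_ds = list(
    consensus = "synref_rdrp_ds_1",
    motifs = list(b1 = c(250L, 262L), b2 = c(330L, 342L))
  ),
  ntpase = list(consensus = "synref_ntpase_1", motifs = list()),
  peptidoglycan_hydrolase = list(
    consensus = "synref_peptidoglycan_hydrolase_1", motifs = list()
  )
)

# Fraction of the model self-score required for a domain call, and of a
# motif's self-score for that motif to count as covered. Calibrated so that
# every packaged reference protein passes on its own family model while
# composition-shuffled proteins fail (see tests); divergent but
# block-conserved family members retain large margins.
.MODEL_SCORE_FRACTION <- 0.04
.MODEL_SCORE_FLOOR <- 60L
.MOTIF_SCORE_FRACTION <- 0.60

#' Packaged reference phage proteins
#'
#' Returns the reference protein set shipped with the package: a synthetic,
#' deterministically generated stand-in for the reference ssRNA/dsRNA
#' bacteriophage proteins (RdRp, maturation, coat, lysin, NTPase,
#' peptidoglycan hydrolase families). These sequences seed the synthetic
#' community generator, serve as translated-search queries, and are the
#' source of the packaged domain models.
#'
#' @param role optional character; restrict to one domain family
#'   (e.g. `"rdrp_ss"`, `"maturation"`).
#' @return an [Biostrings::AAStringSet]
#' @export
referenceProteins <- function(role = NULL) {
  aa <- .cache_get("reference_proteins", {
    f <- system.file("extdata", "synthetic_reference_proteins.faa",
                     package = "rnaphage", mustWork = TRUE)
    Biostrings::readAAStringSet(f)
  })
  names(aa) <- sub(" .*", "", names(aa))
  if (!is.null(role)) {
    want <- paste0("synref_", role, "_")
    aa <- aa[startsWith(names(aa), want)]
    if (!length(aa)) .stopf("unknown reference role '%s'", role)
  }
  aa
}

.reference_role <- function(name) {
  sub("_[0-9]+$", "", sub("^synref_", "", name))
}

#' Packaged domain motif models
#'
#' Builds the position-specific domain models used by [scanDomains()]. One
#' model per phage domain family; the ssRNA RdRp model records the five
#' palm-motif intervals so hits can report motif coverage.
#'
#' @return a named list of models, each with elements `domain`, `consensus`
#'   (character), `codes` (integer codes), `length`, `threshold` (raw
#'   BLOSUM62 score), and `motifs` (named list with per-motif `codes` and
#'   `threshold`).
#' @export
motifModels <- function() {
  .cache_get("motif_models", {
    refs <- referenceProteins()
    sm <- .search_matrix()
    lapply(setNames(names(.MODEL_DEFS), names(.MODEL_DEFS)), function(dom) {
      def <- .MODEL_DEFS[[dom]]
      cons <- as.character(refs[[def$consensus]])
      codes <- .encode_aa(cons)
      self <- sum(sm[cbind(codes + 1L, codes + 1L)])
      motifs <- lapply(def$motifs, function(iv) {
        mc <- codes[(iv[1] + 1L):iv[2]]
        mself <- sum(sm[cbind(mc + 1L, mc + 1L)])
        list(start = iv[1], end = iv[2], codes = mc,
             threshold = ceiling(.MOTIF_SCORE_FRACTION * mself))
      })
      list(domain = dom, consensus = cons, codes = codes,
           length = length(codes), self_score = self,
           threshold = max(.MODEL_SCORE_FLOOR,
                           ceiling(.MODEL_SCORE_FRACTION * self)),
           motifs = motifs)
    })
  })
}

#' Scan a protein for phage-specific domains
#'
#' Scores a protein against the packaged domain models by best ungapped
#' local segment under BLOSUM62 and reports every model scoring at or above
#' its calibrated threshold. For ssRNA RdRp hits, each palm motif (A-E) is
#' scanned separately and the covered set is reported.
#'
#' @param protein a single amino-acid sequence (character or
#'   [Biostrings::AAString]).
#' @param models model set from [motifModels()]; a character vector of model
#'   names restricts the scan. Unknown names are an error.
#' @param orfId optional identifier copied into the result.
#' @return data.frame with columns `orf`, `domain`, `score`, `threshold`,
#'   `motif_coverage` (comma-collapsed motif names, `NA` for non-RdRp
#'   domains), and the matched interval on the protein
#'   (`protein_start`, `protein_end`; 0-based half-open).
#' @export
scanDomains <- function(protein, models = motifModels(), orfId = NA_character_) {
  if (is.character(models)) {
    all <- motifModels()
    bad <- setdiff(models, names(all))
    if (length(bad)) .stopf("unknown domain model(s): %s",
                            paste(bad, collapse = ", "))
    models <- all[models]
  }
  protein <- as.character(protein)
  stopifnot(length(protein) == 1L)
  codes <- .encode_aa(protein)
  sm <- .search_matrix()
  out <- lapply(models, function(mod) {
    if (length(codes) < 1L) return(NULL)
    hit <- cpp_ungapped_local(codes, mod$codes, sm)
    if (hit$score < mod$threshold) return(NULL)
    cov <- NA_character_
    if (mod$domain == "rdrp_ss") {
      got <- vapply(mod$motifs, function(m) {
        mh <- cpp_ungapped_local(codes, m$codes, sm)
        mh$score >= m$threshold
      }, logical(1))
      cov <- paste(names(mod$motifs)[got], collapse = ",")
    }
    data.frame(orf = orfId, domain = mod$domain, score = hit$score,
               threshold = mod$threshold, motif_coverage = cov,
               protein_start = hit$a_start, protein_end = hit$a_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(orf = character(), domain = character(),
                      score = integer(), threshold = integer(),
                      motif_coverage = character(),
                      protein_start = integer(), protein_end = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Is an RdRp palm domain complete?
#'
#' A single-stranded-RNA RdRp domain hit is palm-complete when all five
#' conserved palm motifs (A-E) are covered. Non-RdRp hits are an error.
#'
#' @param hit one row of the data.frame returned by [scanDomains()].
#' @return logical
#' @export
palmComplete <- function(hit) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    domain <- hit$domain
    cov <- hit$motif_coverage
  } else {
    domain <- hit[["domain"]]
    cov <- hit[["motif_coverage"]]
  }
  if (!identical(domain, "rdrp_ss")) {
    .stopf("palm completeness is defined only for rdrp_ss hits, got '%s'",
           domain)
  }
  got <- strsplit(ifelse(is.na(cov), "", cov), ",", fixed = TRUE)[[1]]
  all(c("A", "B", "C", "D", "E") %in% got)
}
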