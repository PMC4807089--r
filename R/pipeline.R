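# End-to-end pipeline: simulate -> triage -> assemble -> annotate ->
# dereplicate -> species table -> tree (-> prevalence), with a manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: E-value cutoff
#' `1e-4`, dataset selection at `>= 10` significant reads, contig length
#' cutoff 750 nt (strict), phylotype threshold 0.70 nucleotide identity
#' (strict), species cutoffs 70/60/50/40 percent amino-acid identity
#' (non-strict), 100 bootstrap replicates. Overrides are recorded in the
#' run manifest; absence of an override means the default was used.
#'
#' @param community a [communitySpec()] describing the synthetic input
#'   (ignored when `reads` is supplied).
#' @param reads optional [Biostrings::DNAStringSet] (or FASTA path): use
#'   these reads instead of simulating.
#' @param queries protein queries for triage; defaults to the packaged
#'   reference proteins.
#' @param evalue significance cutoff for translated hits.
#' @param minReads dataset selection threshold (distinct significant reads).
#' @param minContig contig length cutoff, nt.
#' @param minOverlap,maxMismatch greedy assembly parameters.
#' @param minAa minimal ORF protein length.
#' @param minGeneFrac minimal fraction of the domain model a gene ORF must
#'   cover to be used for phylotype clustering and species delimitation.
#' @param phylotypeThreshold nucleotide identity threshold for phylotypes.
#' @param speciesCutoffs percent amino-acid identity cutoffs.
#' @param bootstrap bootstrap replicates for the representatives' tree.
#' @param includeReferences also place the packaged reference RdRp proteins
#'   in the species-table identity matrix.
#' @param detections optional detection table (see
#'   [buildPresenceMatrix()]) for the prevalence stage.
#' @param seed master RNG seed.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(community = communitySpec(seed = seed),
                           reads = NULL,
                           queries = NULL,
                           evalue = 1e-4,
                           minReads = 10L,
                           minContig = 750L,
                           minOverlap = 30L,
                           maxMismatch = 0.02,
                           minAa = 50L,
                           minGeneFrac = 0.75,
                           phylotypeThreshold = 0.70,
                           speciesCutoffs = c(70, 60, 50, 40),
                           bootstrap = 100L,
                           includeReferences = FALSE,
                           detections = NULL,
                           seed = 1L) {
  structure(list(community = community, reads = reads, queries = queries,
                 evalue = evalue, min_reads = as.integer(minReads),
                 min_contig = as.integer(minContig),
                 min_overlap = as.integer(minOverlap),
                 max_mismatch = maxMismatch, min_aa = as.integer(minAa),
                 min_gene_frac = minGeneFrac,
                 phylotype_threshold = phylotypeThreshold,
                 species_cutoffs = speciesCutoffs,
                 bootstrap = as.integer(bootstrap),
                 include_references = includeReferences,
                 detections = detections, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# gene sequences (nt) and proteins for the best-scoring domain ORF per
# contig. Fragmentary gene ORFs (covering less than minFrac of the domain
# model) are not used: under pairwise gap deletion a conserved-block
# fragment aligns at inflated identity to everything and would chain
# unrelated phylotypes.
.extract_gene <- function(contigs, orfs, hits, domains, minFrac = 0.75) {
  h <- hits[hits$domain %in% domains, , drop = FALSE]
  models <- motifModels()
  out <- list()
  for (ct in unique(h$contig)) {
    hh <- h[h$contig == ct, , drop = FALSE]
    hh <- hh[order(-hh$score), , drop = FALSE]
    keep <- vapply(seq_len(nrow(hh)), function(i) {
      o <- orfs[orfs$orf_id == hh$orf[i], , drop = FALSE]
      nrow(o) == 1L && o$aa_len >= minFrac * models[[hh$domain[i]]]$length
    }, logical(1))
    hh <- hh[keep, , drop = FALSE]
    if (!nrow(hh)) next
    orf <- orfs[orfs$orf_id == hh$orf[1], , drop = FALSE]
    if (!nrow(orf)) next
    nt <- substring(as.character(contigs[[ct]]), orf$start + 1L, orf$end)
    if (orf$strand == "-") {
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    }
    out[[ct]] <- list(nt = nt, protein = orf$protein, orf_id = orf$orf_id)
  }
  out
}

#' Run the discovery pipeline end to end
#'
#' Executes the stages in order, writing plain-file outputs
#' (FASTA/TSV/JSON/Newick) and a `manifest.json` listing every parameter
#' and per-stage counts to `outDir`. Re-running with the same configuration
#' and seed reproduces identical outputs (the manifest carries no
#' timestamps). A dataset failing triage halts the pipeline after the
#' triage stage with status `"not_selected"`.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @return invisibly, a list with the per-stage results (`community`,
#'   `triage`, `contigs`, `partial_genomes`, `phylotypes`, `species`,
#'   `tree`, `prevalence`, `manifest`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "rnaphage",
    version = as.character(utils::packageVersion("rnaphage")),
    parameters = list(
      evalue = config$evalue, min_reads = config$min_reads,
      min_contig = config$min_contig, min_overlap = config$min_overlap,
      max_mismatch = config$max_mismatch, min_aa = config$min_aa,
      min_gene_frac = config$min_gene_frac,
      phylotype_threshold = config$phylotype_threshold,
      species_cutoffs = config$species_cutoffs,
      bootstrap = config$bootstrap,
      include_references = config$include_references,
      seed = config$seed),
    stages = list())
  result <- list()

  finish <- function(status) {
    manifest$status <<- status
    files <- list.files(outDir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$outputs <<- as.list(tools::md5sum(files))
    names(manifest$outputs) <<- basename(files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <<- manifest
    invisible(result)
  }

  ## stage: input -------------------------------------------------------------
  if (is.null(config$reads)) {
    community <- simulateCommunity(config$community)
    writeCommunity(community, outDir)
    rds <- reads(community)
    result$community <- community
    manifest$parameters$community <- unclass(config$community)[
      setdiff(names(unclass(config$community)), "orf_aa")]
    .stage_log("simulate", "%d phylotypes, %d genomes, %d reads",
               length(unique(genomeTruth(community)$phylotype)),
               length(genomes(community)), length(rds))
  } else {
    rds <- if (is.character(config$reads)) {
      Biostrings::readDNAStringSet(config$reads)
    } else config$reads
    .stage_log("input", "%d reads supplied", length(rds))
  }
  manifest$stages$input <- list(n_reads = length(rds))

  ## stage: triage ------------------------------------------------------------
  queries <- config$queries %||% referenceProteins()
  hits <- translatedSearch(queries, rds, evalueMax = config$evalue)
  utils::write.table(hits, file.path(outDir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  triage <- triageDataset(hits, config$min_reads, config$evalue)
  jsonlite::write_json(triage, file.path(outDir, "triage.json"),
                       auto_unbox = TRUE)
  manifest$stages$triage <- triage
  result$triage <- triage
  .stage_log("triage", "%d significant reads -> %s",
             triage$n_significant_reads,
             if (triage$selected) "selected" else "not selected")
  if (!triage$selected) return(finish("not_selected"))

  ## stage: assembly ----------------------------------------------------------
  contigs <- greedyAssemble(rds, config$min_overlap, config$max_mismatch)
  kept <- filterContigs(contigs, config$min_contig)
  Biostrings::writeXStringSet(
    setNames(kept, sprintf("%s n_reads=%d", names(kept),
                           S4Vectors::mcols(kept)$n_reads)),
    file.path(outDir, "contigs.fasta"))
  names(kept) <- sub(" .*", "", names(kept))
  manifest$stages$assembly <- list(n_contigs = length(contigs),
                                   n_contigs_kept = length(kept))
  result$contigs <- kept
  .stage_log("assemble", "%d contigs, %d longer than %d nt",
             length(contigs), length(kept), config$min_contig)
  if (!length(kept)) return(finish("no_contigs"))

  ## stage: annotation --------------------------------------------------------
  orfs <- do.call(rbind, lapply(names(kept), function(ct) {
    findOrfs(kept[[ct]], minAa = config$min_aa, contigId = ct)
  }))
  dhits <- scanOrfDomains(orfs)
  pg <- classifyPartialGenomes(kept, orfs, dhits, config$min_contig)
  utils::write.table(orfs[, names(orfs) != "protein"],
                     file.path(outDir, "orfs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dhits, file.path(outDir, "domain_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$annotation <- genomeSummary(pg)
  result$partial_genomes <- pg
  .stage_log("annotate", "%d partial genomes (rdrp %d, maturation %d, both %d)",
             genomeSummary(pg)$n_partial_genomes, genomeSummary(pg)$n_with_rdrp,
             genomeSummary(pg)$n_with_maturation, genomeSummary(pg)$n_with_both)
  if (!genomeSummary(pg)$n_partial_genomes) return(finish("no_partial_genomes"))

  ## stage: dereplication -----------------------------------------------------
  acc <- partialGenomes(pg)
  rdrp_genes <- .extract_gene(acc, orfTable(pg), domainHits(pg),
                              c("rdrp_ss", "rdrp_ds"), config$min_gene_frac)
  mat_genes <- .extract_gene(acc, orfTable(pg), domainHits(pg),
                             "maturation", config$min_gene_frac)
  gdf <- data.frame(
    id = names(acc), length = Biostrings::width(acc),
    rdrp = vapply(names(acc), function(ct)
      rdrp_genes[[ct]]$nt %||% NA_character_, character(1)),
    maturation = vapply(names(acc), function(ct)
      mat_genes[[ct]]$nt %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)
  phylo <- clusterPhylotypes(gdf, "either", config$phylotype_threshold)
  utils::write.table(phylo, file.path(outDir, "phylotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # conservative estimate: clusters containing a qualifying RdRp gene (RNA
  # viruses carry one RdRp, so maturation-only clusters may be 5' halves of
  # genomes already counted)
  has_rdrp_gene <- vapply(phylo$members, function(ms) {
    any(strsplit(ms, ",")[[1]] %in% names(rdrp_genes))
  }, logical(1))
  manifest$stages$dereplication <- list(
    n_phylotypes = nrow(phylo),
    n_phylotypes_rdrp = sum(has_rdrp_gene))
  result$phylotypes <- phylo
  result$n_phylotypes_rdrp <- sum(has_rdrp_gene)
  .stage_log("dereplicate", "%d phylotypes (%d with RdRp)", nrow(phylo),
             sum(has_rdrp_gene))

  ## stage: species table -----------------------------------------------------
  reps <- phylo$representative
  rep_prot <- vapply(reps, function(ct)
    rdrp_genes[[ct]]$protein %||% NA_character_, character(1))
  names(rep_prot) <- phylo$phylotype
  rep_prot <- rep_prot[!is.na(rep_prot)]
  species <- NULL
  if (length(rep_prot) >= 1L) {
    prot_set <- rep_prot
    if (config$include_references) {
      refs <- referenceProteins("rdrp_ss")
      prot_set <- c(prot_set, setNames(as.character(refs), names(refs)))
    }
    im <- identityMatrix(prot_set, "aa")
    species <- speciesTable(im, config$species_cutoffs)
    utils::write.table(species, file.path(outDir, "species_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$species <- as.list(setNames(species$n_species,
                                                paste0("cutoff_", species$cutoff)))
    result$species <- species
    result$rdrp_identity <- im
    .stage_log("species-table", "%s",
               paste(sprintf("%d%%: %d", species$cutoff, species$n_species),
                     collapse = ", "))
  }

  ## stage: tree --------------------------------------------------------------
  tree <- NULL
  if (length(rep_prot) >= 3L) {
    widths <- nchar(rep_prot)
    if (length(unique(widths)) == 1L) {
      tree <- bootstrapSupport(rep_prot, nReps = config$bootstrap,
                               seed = config$seed, distance = "p")
      manifest$stages$tree <- list(taxa = length(rep_prot),
                                   bootstrap = config$bootstrap)
    } else {
      d <- 1 - identities(identityMatrix(rep_prot, "aa"))
      tree <- njTree(d)
      manifest$stages$tree <- list(taxa = length(rep_prot), bootstrap = 0L,
                                   note = "unequal protein lengths: pairwise p-distances, no bootstrap")
    }
    ape::write.tree(tree, file.path(outDir, "tree.nwk"))
    result$tree <- tree
    .stage_log("tree", "NJ tree over %d representatives", length(rep_prot))
  }

  ## stage: prevalence --------------------------------------------------------
  if (!is.null(config$detections)) {
    det <- config$detections
    if (is.character(det)) det <- utils::read.delim(det)
    pm <- buildPresenceMatrix(det)
    writePresenceMatrix(pm, file.path(outDir, "presence.tsv"))
    summ <- summarizePrevalence(pm)
    jsonlite::write_json(summ[c("n_specimens", "n_specimens_ge1",
                                "n_specimens_ge2")],
                         file.path(outDir, "prevalence.json"),
                         auto_unbox = TRUE)
    manifest$stages$prevalence <- summ[c("n_specimens", "n_specimens_ge1",
                                         "n_specimens_ge2")]
    result$prevalence <- summ
    .stage_log("prevalence", "%d/%d specimens positive",
               summ$n_specimens_ge1, summ$n_specimens)
  }

  finish("complete")
}
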