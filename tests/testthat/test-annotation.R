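# ORF prediction, overlap measurement, domain scanning, palm completeness,
# partial-genome classification.

test_that("a constructed complete ORF is predicted exactly", {
  syn <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  body <- withr::with_seed(41, paste(sample(sense, 99, replace = TRUE),
                                     collapse = ""))
  contig <- paste0("CCC", "ATG", body, "TAA", "CCC")
  orfs <- findOrfs(contig, minAa = 50)
  main <- orfs[orfs$strand == "+" & orfs$aa_len == 100, ]
  expect_identical(nrow(main), 1L)
  expect_identical(main$start, 3L)
  expect_identical(main$end, 3L + 303L)
  expect_false(main$partial5); expect_false(main$partial3)
  expect_identical(substr(main$protein, 1, 1), "M")
})

test_that("ORFs of simulated genomes are recovered at their planted ends", {
  t <- leviviralTemplate(4000L)
  g <- simulateGenome(t, seed = 42)
  orfs <- findOrfs(g$sequence, minAa = 50)
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    hit <- orfs[orfs$end == f$end & orfs$strand == "+" &
                (f$end - orfs$start) %% 3 == 0, ]
    expect_identical(nrow(hit), 1L)
    # the finder may extend 5' to an upstream in-frame start; never shorten
    expect_lte(hit$start, f$start)
    expect_match(hit$protein, paste0(substr(f$protein, 2, nchar(f$protein)),
                                     "$"))
  }
})

test_that("findOrfs matches the exhaustive per-frame oracle", {
  for (seed in 1:5) {
    s <- withr::with_seed(100 + seed, rand_dna(3000))
    got <- findOrfs(s, minAa = 30)
    exp <- oracle_orfs(s, min_aa = 30)
    expect_identical(orf_key(got), orf_key(exp))
  }
})

test_that("ORF overlap is plain interval arithmetic", {
  a <- list(contig = "c", start = 0L, end = 300L)
  b <- list(contig = "c", start = 259L, end = 600L)
  expect_identical(measureOrfOverlap(a, b), 41L)
  expect_identical(measureOrfOverlap(b, a), 41L)
  d <- list(contig = "c", start = 400L, end = 500L)
  expect_identical(measureOrfOverlap(a, d), 0L)
  e <- list(contig = "other", start = 0L, end = 30L)
  expect_error(measureOrfOverlap(a, e), "different contigs")
})

test_that("every packaged reference protein is recognised by its own model", {
  refs <- referenceProteins()
  for (nm in names(refs)) {
    role <- rnaphage:::.reference_role(nm)
    hits <- scanDomains(as.character(refs[[nm]]))
    expect_true(role %in% hits$domain, label = paste(nm, "self-recognition"))
  }
  # the RdRp consensus saturates all five palm motifs
  rd <- scanDomains(as.character(referenceProteins("rdrp_ss")[[1]]))
  rd <- rd[rd$domain == "rdrp_ss", ]
  expect_identical(rd$motif_coverage, "A,B,C,D,E")
  expect_true(palmComplete(rd))
  # a maturation reference hits maturation but not the RdRp model
  mat <- scanDomains(as.character(referenceProteins("maturation")[[1]]))
  expect_true("maturation" %in% mat$domain)
  expect_false("rdrp_ss" %in% mat$domain)
  expect_error(scanDomains("MKT", models = "no_such_model"), "unknown")
})

test_that("composition-shuffled proteins fail the domain thresholds", {
  cons <- as.character(referenceProteins("rdrp_ss")[[1]])
  v <- strsplit(cons, "")[[1]]
  n_hit <- withr::with_seed(43, {
    sum(vapply(1:100, function(i) {
      shuf <- paste(sample(v), collapse = "")
      nrow(scanDomains(shuf)) > 0
    }, logical(1)))
  })
  expect_lte(n_hit, 5)  # nulls fail in >= 95% of shuffles
})

test_that("palm completeness requires all five motifs", {
  expect_true(palmComplete(list(domain = "rdrp_ss",
                                motif_coverage = "A,B,C,D,E")))
  expect_false(palmComplete(list(domain = "rdrp_ss",
                                 motif_coverage = "A,B,C,D")))
  expect_false(palmComplete(list(domain = "rdrp_ss", motif_coverage = NA)))
  expect_error(palmComplete(list(domain = "coat", motif_coverage = NA)),
               "rdrp_ss")
})

test_that("planted truncations are counted exactly by palm completeness", {
  models <- motifModels()
  cons <- models$rdrp_ss$consensus
  withr::with_seed(44, {
    n <- 30
    full <- sample(n, 18)
    hits <- lapply(seq_len(n), function(i) {
      prot <- if (i %in% full) cons else substr(cons, 1, 395)  # motif E lost
      h <- scanDomains(prot)
      h[h$domain == "rdrp_ss", ]
    })
    passed <- vapply(hits, function(h) nrow(h) == 1 && palmComplete(h),
                     logical(1))
    expect_identical(sum(passed), 18L)
    expect_setequal(which(passed), full)
  })
})

test_that("partial-genome classification applies length and domain rules", {
  t <- leviviralTemplate(4000L)
  g <- simulateGenome(t, seed = 45)
  # contig 1: a genuine phage genome fragment (> 750, has domains)
  c1 <- substring(g$sequence, 1, 3200)
  # contig 2: long random sequence, no domains
  c2 <- withr::with_seed(46, rand_dna(3000))
  # contig 3: phage fragment but too short
  c3 <- substring(g$sequence, 1900, 2600)
  contigs <- Biostrings::DNAStringSet(c(c1 = c1, c2 = c2, c3 = c3))
  orfs <- do.call(rbind, lapply(names(contigs), function(ct)
    findOrfs(contigs[[ct]], contigId = ct)))
  hits <- scanOrfDomains(orfs)
  pg <- classifyPartialGenomes(contigs, orfs, hits)
  s <- genomeSummary(pg)
  expect_identical(names(partialGenomes(pg)), "c1")
  expect_identical(s$n_partial_genomes, 1L)
  expect_identical(s$n_with_rdrp, 1L)
  expect_identical(s$n_with_maturation, 1L)
  expect_identical(s$n_with_both, 1L)
  expect_lte(s$n_with_both, min(s$n_with_rdrp, s$n_with_maturation))
})
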