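# Synthetic community generator: templates, genome realisation, controlled
# divergence, shotgun reads, ground truth.

test_that("genome templates validate coordinates, frames and overlaps", {
  orfs <- data.frame(role = "coat", start = 10L, end = 100L)
  expect_silent(genomeTemplate("t", 200L, orfs))
  expect_error(genomeTemplate("t", 90L, orfs), "outside")
  expect_error(genomeTemplate("t", 200L,
                              data.frame(role = "coat", start = 10L, end = 99L)),
               "multiples of 3")
  # declared overlap must equal the coordinate overlap
  orfs2 <- data.frame(role = c("novel", "maturation"),
                      start = c(0L, 259L), end = c(300L, 600L + 259L))
  expect_error(genomeTemplate("t", 1000L, orfs2,
                              overlaps = data.frame(a = 1, b = 2, overlap_nt = 40L)),
               "declared overlap")
  expect_silent(genomeTemplate("t", 1000L, orfs2,
                               overlaps = data.frame(a = 1, b = 2, overlap_nt = 41L)))
})

test_that("simulated genomes realise their ORF layout cleanly", {
  t <- leviviralTemplate(4000L, name = "g")
  g <- simulateGenome(t, seed = 11)
  expect_identical(nchar(g$sequence), 4000L)
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(g$features))) {
    s <- g$features$start[i]; e <- g$features$end[i]
    orf <- substring(g$sequence, s + 1, e)
    cods <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
    expect_identical(cods[1], "ATG")
    expect_true(gc[cods[length(cods)]] == "*")
    expect_false(any(gc[cods[-length(cods)]] == "*"))
  }
  # determinism: same template + seed twice -> identical sequence
  expect_identical(simulateGenome(t, seed = 11)$sequence, g$sequence)
  expect_false(identical(simulateGenome(t, seed = 12)$sequence, g$sequence))
})

test_that("a novel 5' ORF overlapping the maturation gene by 259 nt is realised", {
  t <- leviviralTemplate(5000L, extraOrfAa = 400L, extraOverlapNt = 259L)
  g <- simulateGenome(t, seed = 4)
  nov <- g$features[g$features$role == "novel", ]
  mat <- g$features[g$features$role == "maturation", ]
  expect_gt(nov$end - nov$start, 1200L)  # > 1.20 kb novel ORF
  expect_identical(measureOrfOverlap(nov, mat), 259L)
  # both ORFs still decode cleanly despite the shared region
  gc <- Biostrings::GENETIC_CODE
  for (f in list(nov, mat)) {
    orf <- substring(g$sequence, f$start + 1, f$end)
    cods <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
    expect_false(any(gc[cods[-length(cods)]] == "*"))
  }
})

test_that("evolvePopulation plants the requested divergence exactly", {
  anc <- withr::with_seed(5, rand_dna(1000))
  expect_identical(evolvePopulation(anc, 1.0, 3, seed = 1), rep(anc, 3))
  # oracle: planted substitutions / length; the aligner must agree
  v <- evolvePopulation(anc, 0.90, 5, seed = 7)
  for (x in v) {
    expect_identical(hamming_identity(anc, x), 0.90)
    al <- globalAlignIdentity(anc, x, "nt")
    expect_gte(al$identity, 0.88)
    expect_lte(al$identity, 0.92)
  }
  v50 <- evolvePopulation(anc, 0.50, 2, seed = 8)
  for (x in v50) {
    expect_lt(abs(hamming_identity(anc, x) - 0.50), 0.02)
  }
  expect_error(evolvePopulation(anc, 0, 1), "targetIdentity")
  expect_error(evolvePopulation(anc, 1.2, 1), "targetIdentity")
})

test_that("ORF-aware evolution preserves reading frames and conserved blocks", {
  t <- leviviralTemplate(4000L)
  g <- simulateGenome(t, seed = 2)
  blocks <- conservedBlocks(g$features)
  v <- evolvePopulation(g$sequence, 0.60, 1, seed = 3, orfAware = TRUE,
                        features = g$features, conservedBlocks = blocks)
  expect_equal(hamming_identity(g$sequence, v), 0.60, tolerance = 1e-3)
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(g$features))) {
    s <- g$features$start[i]; e <- g$features$end[i]
    orf <- substring(v, s + 1, e)
    cods <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
    expect_false(any(gc[cods[-length(cods)]] == "*"))
  }
  # conserved blocks carry only synonymous change: proteins identical there
  aa_of <- function(sq, s, e) {
    as.character(Biostrings::translate(Biostrings::DNAString(substring(sq, s + 1, e))))
  }
  for (b in seq_len(nrow(blocks))) {
    expect_identical(aa_of(v, blocks$start[b], blocks$end[b]),
                     aa_of(g$sequence, blocks$start[b], blocks$end[b]))
  }
})

test_that("shotgun read counts, errors, strands and background behave as modelled", {
  g <- withr::with_seed(2, Biostrings::DNAStringSet(c(g1 = rand_dna(4000))))
  sim <- shotgunReads(g, readLength = 200, coverage = 20, errorRate = 0,
                      seed = 21)
  # Poisson oracle: ~400 reads within 3 sigma
  expect_lt(abs(length(sim$reads) - 400), 3 * sqrt(400))
  # error rate 0: every read is an exact substring of the genome or its rc
  gs <- as.character(g[[1]]); grc <- revcomp_chr(gs)
  hay <- paste(gs, grc, sep = "|")
  for (r in as.character(sim$reads)) {
    expect_true(grepl(r, hay, fixed = TRUE))
  }
  # strand balance within binomial 3 sigma of 0.5
  nminus <- sum(sim$truth$strand == "-")
  expect_lt(abs(nminus - length(sim$reads) / 2), 3 * sqrt(length(sim$reads) / 4))
  # background fraction ~ 0.5 of the total
  simbg <- shotgunReads(g, readLength = 200, coverage = 20, errorRate = 0,
                        backgroundFraction = 0.5, seed = 22)
  nbg <- sum(simbg$truth$source == "background")
  expect_lt(abs(nbg - length(simbg$reads) / 2),
            3 * sqrt(length(simbg$reads) / 4) + 3)
  # every read has exactly one truth record
  expect_identical(sort(simbg$truth$read), sort(names(simbg$reads)))
  expect_error(shotgunReads(g, readLength = 5000), "exceeds")
  expect_error(shotgunReads(g, coverage = 0), "coverage")
})

test_that("community simulation is deterministic and honours planted identities", {
  sp <- communitySpec(nPhylotypes = 3L, variantsPerPhylotype = 2L,
                      coverage = 2, genomeLength = 4000L,
                      variantTruncMax = 0L, seed = 77L)
  c1 <- simulateCommunity(sp)
  c2 <- simulateCommunity(sp)
  expect_identical(as.character(genomes(c1)), as.character(genomes(c2)))
  expect_identical(as.character(reads(c1)), as.character(reads(c2)))
  expect_identical(readTruth(c1), readTruth(c2))
  # planted-identity recovery on whole genomes (no truncation)
  gt <- genomeTruth(c1)
  gs <- as.character(genomes(c1))
  for (i in 1:(length(gs) - 1)) {
    for (j in (i + 1):length(gs)) {
      h <- hamming_identity(gs[i], gs[j])
      if (gt$phylotype[i] == gt$phylotype[j]) {
        expect_gt(h, 0.70)
      } else {
        expect_lt(h, 0.70)
      }
    }
  }
  # read truth joins phylotypes through source genomes
  tr <- readTruth(c1)
  phage <- tr$phylotype != "background"
  expect_identical(tr$phylotype[phage],
                   gt$phylotype[match(tr$source[phage], gt$genome)])
})
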