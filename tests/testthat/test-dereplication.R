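# Pairwise identity, phylotype clustering, species counting, amplicon
# matrices, nomenclature.

test_that("global alignment identity follows the p-distance convention", {
  r <- globalAlignIdentity("ACGTACGT", "ACGTACGT", "nt")
  expect_identical(r$identity, 1)
  expect_identical(r$mismatches, 0L)
  r2 <- globalAlignIdentity("ACGT", "ACGA", "nt")
  expect_identical(r2$identity, 0.75)
  expect_identical(r2$mismatches, 1L)
  expect_identical(r2$aligned_positions, 4L)
  expect_error(globalAlignIdentity("", "ACGT", "nt"), "empty")
  # gap columns are deleted pairwise: a clean terminal truncation keeps
  # gap-deleted identity at 1 while span identity also stays 1 (overhang)
  r3 <- globalAlignIdentity("ACGTACGTACGT", "ACGTACGT", "nt")
  expect_identical(r3$identity, 1)
  expect_identical(r3$span_identity, 1)
  # an internal mismatch region counts against span identity
  expect_lte(r2$span_identity, r2$identity)
})

test_that("alignment scores equal an independent DP oracle", {
  withr::with_seed(50, {
    for (i in 1:25) {
      a <- rand_dna(sample(10:60, 1))
      b <- rand_dna(sample(10:60, 1))
      got <- globalAlignIdentity(a, b, "nt")
      expect_identical(got$score,
                       as.integer(oracle_global_score(a, b, nt_score_fun, 5, 2)))
    }
    for (i in 1:15) {
      a <- rand_prot(sample(10:50, 1))
      b <- rand_prot(sample(10:50, 1))
      got <- globalAlignIdentity(a, b, "aa")
      expect_identical(got$score,
                       as.integer(oracle_global_score(a, b, blosum_score_fun,
                                                      11, 1)))
    }
  })
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  withr::with_seed(51, {
    for (i in 1:10) {
      a <- rand_prot(40); b <- rand_prot(40)
      got <- globalAlignIdentity(a, b, "aa")$score
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
        type = "global", scoreOnly = TRUE)
      expect_identical(as.integer(got), as.integer(ref))
    }
  })
})

test_that("identity matrices are symmetric with unit diagonal", {
  seqs <- withr::with_seed(52, setNames(replicate(4, rand_dna(80)),
                                        paste0("s", 1:4)))
  im <- identityMatrix(seqs, "nt")
  expect_true(isSymmetric(unname(identities(im))))
  expect_identical(unname(diag(identities(im))), rep(1, 4))
  expect_identical(unname(diag(mismatchCounts(im))), rep(0L, 4))
  expect_equal(identities(im),
               1 - mismatchCounts(im) / alignedPositions(im))
})

test_that("near-identical variants collapse into one phylotype", {
  seed <- withr::with_seed(53, rand_dna(900))
  ids <- c(0.85, 0.90, 0.97)
  vars <- vapply(seq_along(ids), function(i)
    evolvePopulation(seed, ids[i], 1, seed = 60 + i), character(1))
  df <- data.frame(id = c("seed", paste0("v", 1:3)),
                   length = c(900L, 900L, 900L, 900L),
                   rdrp = c(seed, vars), maturation = NA_character_,
                   stringsAsFactors = FALSE)
  expect_warning(phy <- clusterPhylotypes(df, "either"), NA)
  expect_identical(nrow(phy), 1L)
  expect_identical(phy$n_members, 4L)
})

test_that("the 70% phylotype threshold is strictly greater-than", {
  a <- withr::with_seed(54, rand_dna(1000))
  b <- evolvePopulation(a, 0.70, 1, seed = 55)   # exactly 0.70
  c_ <- evolvePopulation(a, 0.701, 1, seed = 56) # just above
  expect_identical(hamming_identity(a, b), 0.70)
  two <- clusterPhylotypes(data.frame(id = c("a", "b"), length = 1000L,
                                      rdrp = c(a, b),
                                      stringsAsFactors = FALSE))
  expect_identical(nrow(two), 2L)
  one <- clusterPhylotypes(data.frame(id = c("a", "c"), length = 1000L,
                                      rdrp = c(a, c_),
                                      stringsAsFactors = FALSE))
  expect_identical(nrow(one), 1L)
})

test_that("planted phylotypes are recovered with longest representatives", {
  df <- plant_phylotypes(K = 5, within = 0.90, between = 0.50, seed = 57)
  phy <- clusterPhylotypes(df[, c("id", "length", "rdrp", "maturation")])
  expect_identical(nrow(phy), 5L)
  # representative = longest member = first (untruncated) variant
  expect_setequal(phy$representative, df$id[endsWith(df$id, "_v1")])
  # members agree with the planted labels
  for (i in seq_len(nrow(phy))) {
    members <- strsplit(phy$members[i], ",")[[1]]
    expect_identical(length(unique(df$phylotype[df$id %in% members])), 1L)
  }
})

test_that("genomes lacking both genes are excluded with a warning", {
  a <- withr::with_seed(58, rand_dna(600))
  df <- data.frame(id = c("a", "b"), length = 600L,
                   rdrp = c(a, NA), maturation = NA_character_,
                   stringsAsFactors = FALSE)
  expect_warning(phy <- clusterPhylotypes(df), "lacking")
  expect_identical(nrow(phy), 1L)
  expect_error(suppressWarnings(
    clusterPhylotypes(df[2, , drop = FALSE])), "no genomes")
})

test_that("species counting uses non-strict cutoffs and single linkage", {
  trip <- block_identity_matrix(c(1, 1, 1), within = 1, between = 1)
  expect_identical(countSpecies(trip, 60), 1L)
  four <- block_identity_matrix(rep(1:4, each = 3), within = 0.8,
                                between = 0.3)
  expect_identical(countSpecies(four, 60), 4L)
  # oracle: BFS components on the thresholded graph
  adj <- identities(four) >= 0.6
  expect_identical(countSpecies(four, 60),
                   length(unique(oracle_components(adj))))
  # boundary: a pair exactly at the cutoff merges (>=)
  pair <- block_identity_matrix(c(1, 2), within = 1, between = 0.6)
  expect_identical(countSpecies(pair, 60), 1L)
  expect_identical(countSpecies(pair, 61), 2L)
  # degenerate cutoffs
  expect_identical(countSpecies(four, 0), 1L)
  expect_identical(countSpecies(four, 101), 12L)
})

test_that("species tables are non-decreasing in the cutoff", {
  expect_identical(
    speciesTable(block_identity_matrix(1, 1, 1))$n_species, rep(1L, 4))
  # two-level hierarchy: 4 clusters of 3 in 2 superclusters
  groups <- rep(1:4, each = 3)
  super <- rep(1:2, each = 6)
  n <- 12
  idm <- matrix(0.2, n, n)
  for (s in 1:2) idm[super == s, super == s] <- 0.55
  for (g in 1:4) idm[groups == g, groups == g] <- 0.75
  diag(idm) <- 1
  dimnames(idm) <- list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n))
  im <- methods::new("IdentityMatrix", identity = idm,
                     mismatches = matrix(0L, n, n, dimnames = dimnames(idm)),
                     alignedPositions = matrix(1000L, n, n,
                                               dimnames = dimnames(idm)))
  tab <- speciesTable(im, cutoffs = c(80, 70, 50, 30, 10))
  expect_identical(tab$n_species, c(12L, 4L, 2L, 2L, 1L))
  expect_true(all(diff(tab$n_species[order(tab$cutoff)]) >= 0))
  # random matrices stay monotone
  withr::with_seed(59, {
    for (i in 1:20) {
      k <- sample(4:10, 1)
      m <- matrix(runif(k * k), k, k)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 1
      dimnames(m) <- list(paste0("x", 1:k), paste0("x", 1:k))
      im2 <- methods::new("IdentityMatrix", identity = m,
                          mismatches = matrix(0L, k, k, dimnames = dimnames(m)),
                          alignedPositions = matrix(100L, k, k,
                                                    dimnames = dimnames(m)))
      tab2 <- speciesTable(im2, cutoffs = c(90, 70, 50, 30, 10))
      expect_true(all(diff(tab2$n_species[order(tab2$cutoff)]) >= 0))
    }
  })
})

test_that("amplicon matrices render as Table-style top/bottom grids", {
  a <- withr::with_seed(61, rand_dna(500))
  b <- a
  # plant exactly 5 substitutions
  pos <- withr::with_seed(62, sample(500, 5))
  vb <- strsplit(b, "")[[1]]
  for (p in pos) vb[p] <- setdiff(c("A", "C", "G", "T"), vb[p])[1]
  b <- paste(vb, collapse = "")
  im <- ampliconMatrix(c(x = a, y = b, z = a))
  expect_identical(mismatchCounts(im)["x", "y"], 5L)
  expect_identical(identities(im)["x", "y"], 0.99)
  expect_identical(mismatchCounts(im)["x", "z"], 0L)
  tab <- renderIdentityTable(im)
  expect_identical(tab["x", "y"], "0.99")   # identity above the diagonal
  expect_identical(tab["y", "x"], "5")      # mismatches below
  expect_identical(tab["x", "x"], "")
  expect_error(ampliconMatrix(c(only = a)), "at least 2")
})

test_that("nomenclature encodes source, niche and index", {
  expect_identical(assignName("animal", "VE", 0), "AVE000")
  expect_identical(assignName("environmental", "MS", 13), "EMS013")
  expect_identical(assignName("environmental", "OC", 7), "EOC007")
  expect_error(assignName("animal", "XX", 1), "niche")
  expect_error(assignName("animal", "VE", 1000), "0..999")
})
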