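# Presence/absence matrices, prevalence summaries, persistence, site
# partitioning, TSV round trip.

specimen_table <- function(n = 120) {
  data.frame(specimen = sprintf("sp%03d", seq_len(n)),
             animal = sprintf("an%03d", rep(seq_len(ceiling(n / 2)), 2)[seq_len(n)]),
             site = rep(c("NEPRC", "TNPRC"), length.out = n),
             time_point = rep(c("24", "64"), each = ceiling(n / 2))[seq_len(n)],
             stringsAsFactors = FALSE)
}

det_row <- function(specimen, phylotype, animal = NA, time_point = NA,
                    evidence = "metagenomic", n_reads = 3L) {
  data.frame(specimen = specimen, animal = animal, site = NA,
             time_point = time_point, phylotype = phylotype,
             evidence = evidence, n_reads = n_reads, stringsAsFactors = FALSE)
}

test_that("presence matrices reflect detections cell by cell", {
  spec <- specimen_table(10)
  empty <- det_row("sp001", "PT1")[0, ]
  m0 <- buildPresenceMatrix(empty, specimens = spec)
  expect_identical(dim(presenceCalls(m0)), c(0L, 10L))
  expect_identical(summarizePrevalence(m0)$n_specimens_ge1, 0L)
  one <- buildPresenceMatrix(det_row("sp003", "PT1"), specimens = spec)
  expect_identical(sum(presenceCalls(one)), 1L)
  expect_true(presenceCalls(one)["PT1", "sp003"])
  expect_error(buildPresenceMatrix(det_row("nope", "PT1"), specimens = spec),
               "unknown specimen.*nope")
  expect_error(buildPresenceMatrix(det_row("sp001", "PT1", n_reads = 0L)),
               "n_reads")
})

test_that("a planted detection grid round-trips through the matrix", {
  spec <- specimen_table(120)
  withr::with_seed(80, {
    phylos <- sprintf("PT%02d", 1:6)
    truth <- matrix(runif(6 * 120) < 0.05, 6, 120,
                    dimnames = list(phylos, spec$specimen))
    idx <- which(truth, arr.ind = TRUE)
    det <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k)
      det_row(colnames(truth)[idx[k, 2]], rownames(truth)[idx[k, 1]])))
    m <- buildPresenceMatrix(det, specimens = spec)
    got <- presenceCalls(m)
    present <- rownames(truth)[rowSums(truth) > 0]
    expect_identical(got[present, colnames(truth)],
                     truth[present, , drop = FALSE])
    # summary equals a brute-force recount
    s <- summarizePrevalence(m)
    expect_identical(s$n_specimens_ge1,
                     sum(apply(got, 2, function(cl) sum(cl) >= 1)))
    expect_identical(s$n_specimens_ge2,
                     sum(apply(got, 2, function(cl) sum(cl) >= 2)))
    expect_lte(s$n_specimens_ge2, s$n_specimens_ge1)
    expect_lte(s$n_specimens_ge1, s$n_specimens)
  })
})

test_that("prevalence counting matches a planted 34/10 fixture", {
  spec <- specimen_table(120)
  withr::with_seed(81, {
    pos1 <- sample(spec$specimen, 34)      # at least one phylotype
    pos2 <- sample(pos1, 10)               # at least two
    det <- rbind(
      do.call(rbind, lapply(pos1, det_row, phylotype = "PTA")),
      do.call(rbind, lapply(pos2, det_row, phylotype = "PTB")))
    s <- summarizePrevalence(buildPresenceMatrix(det, specimens = spec))
    expect_identical(s$n_specimens, 120L)
    expect_identical(s$n_specimens_ge1, 34L)
    expect_identical(s$n_specimens_ge2, 10L)
    expect_identical(unname(s$per_phylotype["PTA"]), 34L)
  })
})

test_that("persistence counts animals detected at multiple time points", {
  det <- rbind(
    det_row("s1", "AVE000", animal = "m1", time_point = "24"),
    det_row("s2", "AVE000", animal = "m1", time_point = "64"),
    det_row("s3", "AVE000", animal = "m2", time_point = "24"))
  p <- persistence(det, "AVE000")
  expect_identical(p$n_animals_positive_any, 2L)
  expect_identical(p$n_animals_positive_both_timepoints, 1L)
  expect_error(persistence(det, "PTX"), "unknown phylotype")
  # planted 13-positive / 2-persistent fixture
  withr::with_seed(82, {
    animals <- sprintf("m%02d", 1:13)
    persist <- sample(animals, 2)
    rows <- lapply(seq_along(animals), function(i) {
      tp <- if (animals[i] %in% persist) c("24", "64") else
        sample(c("24", "64"), 1)
      do.call(rbind, lapply(tp, function(t)
        det_row(paste0("s", i, "_", t), "AVE001", animal = animals[i],
                time_point = t, evidence = "rtpcr", n_reads = NA)))
    })
    p2 <- persistence(do.call(rbind, rows), "AVE001")
    expect_identical(p2$n_animals_positive_any, 13L)
    expect_identical(p2$n_animals_positive_both_timepoints, 2L)
    expect_lte(p2$n_animals_positive_both_timepoints,
               p2$n_animals_positive_any)
  })
})

test_that("site partitioning distinguishes clustered from interleaved identities", {
  ids <- matrix(0.85, 6, 6)
  ids[1:3, 1:3] <- 0.98; ids[4:6, 4:6] <- 0.98
  diag(ids) <- 1
  dimnames(ids) <- list(paste0("a", 1:6), paste0("a", 1:6))
  im <- methods::new("IdentityMatrix", identity = ids,
                     mismatches = matrix(0L, 6, 6, dimnames = dimnames(ids)),
                     alignedPositions = matrix(500L, 6, 6,
                                               dimnames = dimnames(ids)))
  r <- sitePartitionCheck(im, c("X", "X", "X", "Y", "Y", "Y"))
  expect_true(r$distinct_clusters)
  expect_gt(r$mean_within, r$mean_between)
  r2 <- sitePartitionCheck(im, c("X", "Y", "X", "Y", "X", "Y"))
  expect_false(r2$distinct_clusters)
  expect_warning(sitePartitionCheck(im, c("X", "X", "X", "Y", "Y", "Z")),
                 "single sequence")
  expect_error(sitePartitionCheck(im, rep("X", 6)), "at least 2 sites")
})

test_that("amplicon site structure built from sequences partitions by site", {
  # two collection sites; within-site amplicons ~0.99, across ~0.95
  withr::with_seed(83, {
    rootA <- rand_dna(400)
    rootB <- evolvePopulation(rootA, 0.955, 1)
    amps <- c(
      setNames(evolvePopulation(rootA, 0.992, 3), paste0("NE", 1:3)),
      setNames(evolvePopulation(rootB, 0.992, 2), paste0("TN", 1:2)))
    im <- ampliconMatrix(amps)
    r <- sitePartitionCheck(im, c("NEPRC", "NEPRC", "NEPRC",
                                  "TNPRC", "TNPRC"))
    expect_true(r$distinct_clusters)
    tab <- renderIdentityTable(im)
    expect_identical(dim(tab), c(5L, 5L))
    expect_true(all(grepl("^0\\.9[0-9]$|^1\\.00$",
                          unlist(tab[upper.tri(tab)]))))
  })
})

test_that("presence matrices round-trip through TSV", {
  spec <- specimen_table(8)
  det <- rbind(det_row("sp002", "PT1"), det_row("sp005", "PT2"),
               det_row("sp005", "PT1"))
  m <- buildPresenceMatrix(det, specimens = spec)
  path <- tempfile(fileext = ".tsv")
  writePresenceMatrix(m, path)
  m2 <- readPresenceMatrix(path)
  expect_identical(presenceCalls(m2), presenceCalls(m))
})
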