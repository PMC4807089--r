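# Alignment trimming, K2P distances, NJ trees, bootstrap support.

make_aln <- function(rows) {
  do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
}

test_that("fully conserved alignments are kept whole", {
  base <- withr::with_seed(70, rand_prot(100))
  m <- make_aln(rep(list(base), 25))
  rownames(m) <- paste0("t", 1:25)
  out <- trimBlocks(m)
  expect_identical(out$kept_columns, 1:100)
  expect_identical(ncol(out$alignment), 100L)
})

test_that("long nonconserved inserts are removed, short ones kept", {
  withr::with_seed(71, {
    n <- 25
    cons <- rand_prot(40)
    rows <- lapply(1:n, function(i) {
      paste0(substr(cons, 1, 20), rand_prot(25), substr(cons, 21, 40))
    })
    m <- make_aln(rows)
    rownames(m) <- paste0("t", 1:n)
    out <- trimBlocks(m)
    # the 25-column random insert (> maxContigNonconserved = 20) is gone
    expect_true(all(out$kept_columns %in% c(1:20, 46:65)))
    expect_identical(out$kept_columns, sort(out$kept_columns))
    # a 10-column insert survives inside a block
    rows2 <- lapply(1:n, function(i) {
      paste0(substr(cons, 1, 20), rand_prot(10), substr(cons, 21, 40))
    })
    m2 <- make_aln(rows2); rownames(m2) <- paste0("t", 1:n)
    out2 <- trimBlocks(m2)
    expect_true(all(21:30 %in% out2$kept_columns))
  })
})

test_that("blocks shorter than the minimum are dropped with a warning", {
  withr::with_seed(72, {
    n <- 25
    m <- make_aln(lapply(1:n, function(i)
      paste0(rand_prot(30), substr("WDH", 1, 3), rand_prot(30))))
    # only a 3-column conserved run: shorter than minBlockLen = 4
    m[, 31:33] <- matrix(rep(c("W", "D", "H"), each = n), n, 3)
    rownames(m) <- paste0("t", 1:n)
    expect_warning(out <- trimBlocks(m), "no alignment block")
    expect_identical(length(out$kept_columns), 0L)
  })
})

test_that("gap policies control gap-column eligibility", {
  base <- strsplit(withr::with_seed(73, rand_prot(30)), "")[[1]]
  m <- do.call(rbind, rep(list(base), 25))
  m[1, 10] <- "-"
  rownames(m) <- paste0("t", 1:25)
  expect_true(10 %in% trimBlocks(m, trimConfig(gapPolicy = "all"))$kept_columns)
  expect_false(10 %in% trimBlocks(m, trimConfig(gapPolicy = "none"))$kept_columns)
  expect_error(trimBlocks(c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("K2P distances match the closed form and ape", {
  expect_identical(k2pDistance("ACGT", "ACGT"), 0)
  # 100 sites: 10 transitions, 5 transversions -> 0.1702 to 4 d.p.
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  expect_equal(round(k2pDistance(a, b), 4), 0.1702)
  expect_error(k2pDistance(chartr("ACGT", "TGCA", "ACGTACGT"), "ACGTACGT"),
               "saturated")
  expect_error(k2pDistance("ACG", "ACGT"), "aligned")
  # cross-check against ape on random diverged pairs
  withr::with_seed(74, {
    for (i in 1:10) {
      x <- rand_dna(300)
      y <- evolvePopulation(x, 0.85, 1)
      got <- k2pDistance(x, y)
      bin <- ape::as.DNAbin(rbind(x = strsplit(x, "")[[1]],
                                  y = strsplit(y, "")[[1]]))
      ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
      expect_equal(got, ref, tolerance = 1e-12)
      expect_gte(got, 0)
    }
  })
})

test_that("NJ recovers additive four- and three-taxon metrics exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)): pairwise path lengths
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 4
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- njTree(d)
  expect_s3_class(tr, "phylo")
  # topology: AB|CD split; total branch length = 8
  expect_equal(sum(tr$edge.length), 8)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), rownames(d)]),
               unname(d), tolerance = 1e-12)
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- njTree(d3)
  len <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(unname(len[c("x", "y", "z")]), c(0.5, 1.5, 2.5))
  expect_error(njTree(d3[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers generating topologies on additive matrices", {
  withr::with_seed(75, {
    for (i in 1:10) {
      tr0 <- ape::rtree(6)
      d <- ape::cophenetic.phylo(tr0)
      tr1 <- njTree(d)
      expect_identical(as.integer(ape::dist.topo(ape::unroot(tr0), tr1)), 0L)
    }
  })
})

test_that("ultrametric matrices give the hierarchical-clustering topology", {
  withr::with_seed(76, {
    tr0 <- ape::rcoal(8)
    d <- ape::cophenetic.phylo(tr0)
    tr1 <- njTree(d)
    expect_identical(as.integer(ape::dist.topo(ape::unroot(tr0), tr1)), 0L)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    tr2 <- ape::as.phylo(hc)
    expect_identical(as.integer(ape::dist.topo(ape::unroot(tr2), tr1)), 0L)
  })
})

test_that("bootstrap supports a planted split and is reproducible", {
  withr::with_seed(77, {
    n_col <- 500
    cladeA <- paste0("a", 1:4); cladeB <- paste0("b", 1:4)
    base <- strsplit(rand_dna(n_col), "")[[1]]
    alt <- base
    split_cols <- sample(n_col, 200)
    # transitions at the split columns separate the clades
    alt[split_cols] <- chartr("ACGT", "GTAC", base[split_cols])
    m <- rbind(do.call(rbind, rep(list(base), 4)),
               do.call(rbind, rep(list(alt), 4)))
    rownames(m) <- c(cladeA, cladeB)
    # taxon-specific noise so within-clade branches resolve
    for (i in 1:8) {
      j <- sample(setdiff(seq_len(n_col), split_cols), 10)
      m[i, j] <- chartr("ACGT", "TGCA", m[i, j])
    }
    tr <- bootstrapSupport(m, nReps = 100, seed = 5, distance = "k2p")
    expect_true(all(tr$node.label >= 0 & tr$node.label <= 100, na.rm = TRUE))
    # the clade split must be near-unanimous
    expect_gte(max(tr$node.label, na.rm = TRUE), 95)
    tr2 <- bootstrapSupport(m, nReps = 100, seed = 5, distance = "k2p")
    expect_identical(tr$node.label, tr2$node.label)
    tr0 <- bootstrapSupport(m, nReps = 0, seed = 5)
    expect_null(tr0$node.label)
  })
})
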