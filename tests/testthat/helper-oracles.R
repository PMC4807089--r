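# Independent oracles and fixture builders shared across the suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_prot <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

hamming_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# ---------------------------------------------------------------------------
# Score-only global (Needleman-Wunsch) and local (Smith-Waterman) affine-gap
# DP, written independently of the package kernels: plain rolling-row R
# loops. A gap of length L costs open + L * ext.
oracle_global_score <- function(a, b, score_fun, open, ext) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  Hprev <- c(0, -(open + ext * seq_len(m)))
  Eprev <- rep(NEG, m + 1)
  Fcol <- rep(NEG, m + 1)
  for (i in seq_len(n)) {
    H <- numeric(m + 1); E <- rep(NEG, m + 1)
    H[1] <- -(open + ext * i)
    Fcol[1] <- H[1]
    for (j in seq_len(m)) {
      E[j + 1] <- max(H[j] - open - ext, E[j] - ext)
      Fcol[j + 1] <- max(Hprev[j + 1] - open - ext, Fcol[j + 1] - ext)
      H[j + 1] <- max(Hprev[j] + score_fun(va[i], vb[j]), E[j + 1],
                      Fcol[j + 1])
    }
    Hprev <- H; Eprev <- E
  }
  Hprev[m + 1]
}

oracle_local_score <- function(a, b, score_fun, open, ext) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  Hprev <- numeric(m + 1)
  Fcol <- rep(NEG, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    H <- numeric(m + 1); E <- rep(NEG, m + 1)
    for (j in seq_len(m)) {
      E[j + 1] <- max(H[j] - open - ext, E[j] - ext)
      Fcol[j + 1] <- max(Hprev[j + 1] - open - ext, Fcol[j + 1] - ext)
      H[j + 1] <- max(0, Hprev[j] + score_fun(va[i], vb[j]), E[j + 1],
                      Fcol[j + 1])
      best <- max(best, H[j + 1])
    }
    Hprev <- H
  }
  best
}

nt_score_fun <- function(x, y) {
  if (x == "N" || y == "N" || x != y) -3 else 2
}

blosum_score_fun <- local({
  B <- NULL
  function(x, y) {
    if (is.null(B)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
      B <<- e$BLOSUM62
    }
    B[x, y]
  }
})

# ---------------------------------------------------------------------------
# Exhaustive per-frame ORF enumeration: a direct positional scan, organised
# differently from findOrfs (explicit per-codon walk with a state machine).
oracle_orfs <- function(seq, min_aa, starts = c("ATG", "GTG", "TTG")) {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_chr(seq)
    for (off in 0:2) {
      ncod <- (L - off) %/% 3
      if (ncod < 1) next
      cods <- substring(s, off + 1 + 3 * (0:(ncod - 1)), off + 3 + 3 * (0:(ncod - 1)))
      aa <- unname(gc[cods]); aa[is.na(aa)] <- "X"
      k <- 1
      seg_begin <- 1
      while (seg_begin <= ncod) {
        # find the closing stop of this segment
        stop_at <- NA
        for (k in seg_begin:ncod) if (aa[k] == "*") { stop_at <- k; break }
        seg_end <- if (is.na(stop_at)) ncod else stop_at
        first_start <- NA
        lim <- if (is.na(stop_at)) seg_end else seg_end - 1
        if (lim >= seg_begin) {
          for (k in seg_begin:lim) {
            if (cods[k] %in% starts) { first_start <- k; break }
          }
        }
        p3 <- is.na(stop_at)
        orfs_here <- list()
        if (seg_begin == 1 && (is.na(first_start) || first_start > 1)) {
          orfs_here[[1]] <- list(c(seg_begin, seg_end), TRUE)
        }
        if (!is.na(first_start)) {
          orfs_here[[length(orfs_here) + 1]] <-
            list(c(first_start, seg_end), FALSE)
        }
        for (oh in orfs_here) {
          orf <- oh[[1]]; p5 <- oh[[2]]
          prot_cods <- if (p3) orf[1]:orf[2] else
            (if (orf[2] - 1 >= orf[1]) orf[1]:(orf[2] - 1) else integer(0))
          if (length(prot_cods) >= min_aa) {
            c0 <- off + 3 * (orf[1] - 1)
            c1 <- off + 3 * orf[2]
            coords <- if (strand == "+") c(c0, c1) else c(L - c1, L - c0)
            out[[length(out) + 1]] <- data.frame(
              start = coords[1], end = coords[2], strand = strand,
              aa_len = length(prot_cods), partial5 = p5, partial3 = p3,
              protein = paste(aa[prot_cods], collapse = ""))
          }
        }
        if (is.na(stop_at)) break
        seg_begin <- stop_at + 1
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      aa_len = integer(), partial5 = logical(),
                      partial3 = logical(), protein = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

orf_key <- function(df) {
  paste(df$start, df$end, df$strand, df$aa_len, df$partial5, df$partial3,
        df$protein, sep = "|")
}

# ---------------------------------------------------------------------------
# Planted phylotype populations for clustering tests: star radiation from a
# compact levivirus-like root, free (unconstrained) evolution, with the
# realized per-gene identities guarded around the 0.70 rule exactly as the
# community generator guards them.
star_divergence <- function(p) {
  disc <- 1 - 4 * (1 - p) / 3
  if (disc <= 0) 0.75 else 0.75 * (1 - sqrt(disc))
}

plant_phylotypes <- function(K, within, between, variants = 2, seed = 1) {
  withr::with_seed(seed, {
    template <- leviviralTemplate(2600, orfAa = c(maturation = 200,
                                                  coat = 60, rdrp = 300))
    root <- simulateGenome(template)
    ft <- root$features
    regions <- ft[ft$role %in% c("maturation", "rdrp"), ]
    gene_of <- function(sq, role, shift = 0) {
      r <- regions[regions$role == role, ]
      substring(sq, r$start - shift + 1, r$end - shift)
    }
    gids <- function(a, b) {
      vapply(c("maturation", "rdrp"), function(role)
        hamming_identity(gene_of(a, role), gene_of(b, role)), numeric(1))
    }
    d_b <- star_divergence(between)
    d_w <- star_divergence(within)
    anc <- character(K)
    for (k in seq_len(K)) {
      repeat {
        cand <- evolvePopulation(root$sequence, 1 - d_b, 1)
        if (k == 1 || all(vapply(seq_len(k - 1), function(j)
          all(gids(cand, anc[j]) <= 0.68), logical(1)))) break
      }
      anc[k] <- cand
    }
    rows <- list()
    for (k in seq_len(K)) {
      repeat {
        vars <- evolvePopulation(anc[k], 1 - d_w, variants)
        ok <- variants == 1 ||
          all(utils::combn(variants, 2, function(ij)
            all(gids(vars[ij[1]], vars[ij[2]]) >= 0.72)))
        if (ok) break
      }
      for (j in seq_along(vars)) {
        sq <- vars[j]
        shift <- 0
        if (j > 1) {           # 5'-truncate so the first variant is longest
          shift <- 50 + 10 * j
          sq <- substring(sq, shift + 1)
        }
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("P%02d_v%d", k, j), phylotype = sprintf("P%02d", k),
          length = nchar(sq),
          rdrp = gene_of(sq, "rdrp", shift),
          maturation = gene_of(sq, "maturation", shift),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# block identity matrix with given group structure
block_identity_matrix <- function(groups, within, between) {
  n <- length(groups)
  nm <- sprintf("s%02d", seq_len(n))
  idm <- matrix(between, n, n, dimnames = list(nm, nm))
  for (g in unique(groups)) {
    i <- which(groups == g)
    idm[i, i] <- within
  }
  diag(idm) <- 1
  mm <- matrix(0L, n, n, dimnames = list(nm, nm))
  mm[idm < 1] <- 100L
  ap <- matrix(1000L, n, n, dimnames = list(nm, nm))
  methods::new("IdentityMatrix", identity = idm, mismatches = mm,
               alignedPositions = ap)
}

# connected components by breadth-first search (independent of igraph)
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
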