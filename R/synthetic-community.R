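# Synthetic levivirus-like community generator with ground truth.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.START_CODONS <- c("ATG", "GTG", "TTG")

.genetic_code <- function() {
  .cache_get("genetic_code", {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- chartr("U", "T", names(gc))
    gc
  })
}

.syn_codons <- function() {
  .cache_get("syn_codons", {
    gc <- .genetic_code()
    split(names(gc), gc)
  })
}

#' Describe a genome template
#'
#' A genome template is the blueprint [simulateGenome()] realises: total
#' length plus an ordered ORF layout (role, coordinates, strand) and the
#' declared overlap between designated adjacent ORFs. Coordinates are
#' 0-based, half-open, forward strand.
#'
#' @param name genome identifier.
#' @param lengthNt total genome length (nt).
#' @param orfs data.frame with columns `role` (one of `maturation`, `coat`,
#'   `rdrp`, or `novel`), `start`, `end`.
#' @param overlaps optional data.frame with columns `a`, `b` (row indices
#'   into `orfs`) and `overlap_nt`, declaring intended ORF overlaps.
#' @return a validated list of class `genome_template`.
#' @export
genomeTemplate <- function(name, lengthNt, orfs, overlaps = NULL) {
  stopifnot(is.data.frame(orfs), all(c("role", "start", "end") %in% names(orfs)))
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  if (any(orfs$start < 0 | orfs$end > lengthNt)) {
    .stopf("template '%s': ORF coordinates outside [0, %d)", name, lengthNt)
  }
  len <- orfs$end - orfs$start
  if (any(len %% 3L != 0L) || any(len < 6L)) {
    .stopf("template '%s': ORF lengths must be positive multiples of 3", name)
  }
  if (!is.null(overlaps)) {
    for (i in seq_len(nrow(overlaps))) {
      a <- orfs[overlaps$a[i], ]
      b <- orfs[overlaps$b[i], ]
      got <- max(0L, min(a$end, b$end) - max(a$start, b$start))
      if (got != overlaps$overlap_nt[i]) {
        .stopf("template '%s': declared overlap %d != coordinate overlap %d",
               name, overlaps$overlap_nt[i], got)
      }
    }
  }
  structure(list(name = name, length_nt = as.integer(lengthNt), orfs = orfs,
                 overlaps = overlaps),
            class = "genome_template")
}

#' Standard levivirus-like template
#'
#' Builds a maturation--coat--RdRp template in the canonical leviviral
#' layout (5' UTR, three non-overlapping ORFs separated by short spacers,
#' 3' UTR). ORF lengths default to the packaged reference protein lengths
#' (maturation gene 1272 nt, matching the reference average of about
#' 1.27 kb); genomes in the 3.7-5.0 kb leviviral range fit the default
#' protein complement. An optional novel 5' ORF overlapping the maturation
#' gene can be added, mirroring the expanded genome organisations seen among
#' divergent phages.
#'
#' @param lengthNt genome length, nt.
#' @param name genome identifier.
#' @param orfAa optional named integer vector overriding protein lengths
#'   (amino acids) for `maturation`, `coat`, `rdrp`; shorter values use a
#'   prefix of the packaged consensus (useful for compact test genomes).
#' @param extraOrfAa if positive, adds a `novel` ORF of this many amino
#'   acids 5' of the maturation gene.
#' @param extraOverlapNt overlap (nt) between the novel ORF's 3' end and the
#'   maturation gene's 5' end.
#' @return a `genome_template`
#' @export
leviviralTemplate <- function(lengthNt = 4000L, name = "genome",
                              orfAa = NULL, extraOrfAa = 0L,
                              extraOverlapNt = 0L) {
  aa <- c(maturation = nchar(as.character(referenceProteins("maturation")[[1]])),
          coat = nchar(as.character(referenceProteins("coat")[[1]])),
          rdrp = nchar(as.character(referenceProteins("rdrp_ss")[[1]])))
  if (!is.null(orfAa)) aa[names(orfAa)] <- orfAa
  nt <- 3L * (aa + 1L)
  spacer <- 40L
  utr5 <- 130L
  core <- sum(nt) + 2L * spacer
  if (extraOrfAa > 0L) {
    utr5 <- max(utr5, 3L * (extraOrfAa + 1L) - extraOverlapNt + 20L)
  }
  utr3 <- lengthNt - utr5 - core
  if (utr3 < 15L) {
    # shrink the 5' UTR / spacers before giving up
    deficit <- 15L - utr3
    take5 <- min(deficit, utr5 - 20L)
    utr5 <- utr5 - take5
    utr3 <- utr3 + take5
    if (utr3 < 15L) {
      .stopf("lengthNt = %d too short for the requested ORF complement (%d nt)",
             lengthNt, core)
    }
  }
  mat_start <- utr5
  coat_start <- mat_start + nt[["maturation"]] + spacer
  rdrp_start <- coat_start + nt[["coat"]] + spacer
  orfs <- data.frame(
    role = c("maturation", "coat", "rdrp"),
    start = c(mat_start, coat_start, rdrp_start),
    end = c(mat_start + nt[["maturation"]], coat_start + nt[["coat"]],
            rdrp_start + nt[["rdrp"]]),
    stringsAsFactors = FALSE
  )
  overlaps <- NULL
  if (extraOrfAa > 0L) {
    nov_end <- mat_start + extraOverlapNt
    nov_start <- nov_end - 3L * (extraOrfAa + 1L)
    if (nov_start < 0L) {
      .stopf("novel ORF of %d aa with %d nt overlap does not fit 5' of the maturation gene",
             extraOrfAa, extraOverlapNt)
    }
    orfs <- rbind(data.frame(role = "novel", start = nov_start, end = nov_end,
                             stringsAsFactors = FALSE), orfs)
    if (extraOverlapNt > 0L) {
      overlaps <- data.frame(a = 1L, b = 2L, overlap_nt = as.integer(extraOverlapNt))
    }
  }
  genomeTemplate(name, lengthNt, orfs, overlaps)
}

# target protein (character scalar) for an ORF of `n_aa` coding amino acids
.role_protein <- function(role, n_aa) {
  if (role %in% c("maturation", "coat")) {
    cons <- as.character(referenceProteins(role)[[1]])
  } else if (role == "rdrp") {
    cons <- as.character(referenceProteins("rdrp_ss")[[1]])
  } else {
    return(NA_character_)  # novel: free protein
  }
  if (nchar(cons) >= n_aa) {
    substr(cons, 1L, n_aa)
  } else {
    paste0(cons, paste(sample(c("A", "S", "L", "G", "T", "V"),
                              n_aa - nchar(cons), replace = TRUE),
                       collapse = ""))
  }
}

#' Realise a genome template as a nucleotide sequence
#'
#' Writes each ORF left to right: the start codon, codons encoding the
#' role's packaged reference protein (or a random protein for `novel`
#' roles), and a stop codon, choosing synonymous codons at random.
#' Positions already fixed by an overlapping ORF are respected; free bases
#' in shared codons are chosen so that no ORF acquires an internal stop and
#' overlapped start/stop codons stay intact. A template whose overlap
#' constraints cannot be satisfied is rejected with a diagnostic.
#' Intergenic and UTR positions are uniform random bases. The same template
#' and seed always give the same sequence.
#'
#' @param template a `genome_template`.
#' @param seed integer RNG seed; `NULL` continues the caller's RNG stream.
#' @return list with `sequence` (character), `features` (data.frame of
#'   realised ORFs with role, 0-based half-open coordinates, strand and
#'   protein), and `name`.
#' @export
simulateGenome <- function(template, seed = NULL) {
  run <- function() {
    # random codon choices can dead-end under overlap constraints; retry
    # with fresh draws before declaring the template unrealisable
    last <- NULL
    for (try in seq_len(25L)) {
      out <- tryCatch(.simulate_genome_impl(template), error = identity)
      if (!inherits(out, "error")) return(out)
      last <- out
    }
    stop(last)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

.simulate_genome_impl <- function(template) {
  L <- template$length_nt
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  fixed <- rep(FALSE, L)
  orfs <- template$orfs
  syn <- .syn_codons()
  gc <- .genetic_code()
  proteins <- character(nrow(orfs))

  # codon constraint check against *other* ORFs: any other-frame codon that
  # becomes fully fixed must be a stop exactly when it is that ORF's
  # terminal codon, and a valid start when it is that ORF's first codon.
  other_ok <- function(pos3, cand, self) {
    for (o in seq_len(nrow(orfs))) {
      if (o == self) next
      os <- orfs$start[o]; oe <- orfs$end[o]
      hit <- pos3[pos3 >= os + 1L & pos3 <= oe]
      if (!length(hit)) next
      test <- chars
      test[pos3] <- strsplit(cand, "")[[1]]
      fx <- fixed
      fx[pos3] <- TRUE
      ci <- unique((hit - os - 1L) %/% 3L)
      for (k in ci) {
        cp <- os + 3L * k + (1:3)
        if (!all(fx[cp])) next
        cod <- paste(test[cp], collapse = "")
        if (k == (oe - os) %/% 3L - 1L) {
          if (!(cod %in% .STOP_CODONS)) return(FALSE)
        } else if (cod %in% .STOP_CODONS) {
          return(FALSE)
        } else if (k == 0L && !(cod %in% .START_CODONS)) {
          return(FALSE)
        }
      }
    }
    TRUE
  }

  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    n_cod <- (e - s) %/% 3L
    n_aa <- n_cod - 2L  # minus start and stop codons
    target <- .role_protein(orfs$role[i], n_aa)
    if (is.na(target)) {
      target <- paste(sample(setdiff(unique(gc), "*"), n_aa, replace = TRUE),
                      collapse = "")
    }
    realised <- character(n_cod)
    for (k in seq_len(n_cod) - 1L) {
      pos <- s + 3L * k + (1:3)
      want <- if (k == 0L) {
        "ATG"
      } else if (k == n_cod - 1L) {
        sample(.STOP_CODONS)
      } else {
        sample(syn[[substr(target, k, k)]])
      }
      fx <- fixed[pos]
      if (any(fx)) {
        consistent <- function(codset) {
          keep <- vapply(codset, function(cd) {
            all(strsplit(cd, "")[[1]][fx] == chars[pos][fx])
          }, logical(1))
          codset[keep]
        }
        cand <- consistent(want)
        if (!length(cand) && k > 0L && k < n_cod - 1L) {
          cand <- consistent(setdiff(names(gc), .STOP_CODONS))
          cand <- sample(cand)
        }
        if (k == 0L) cand <- consistent(.START_CODONS)
        if (k == n_cod - 1L) cand <- consistent(.STOP_CODONS)
      } else {
        cand <- want
      }
      ok <- cand[vapply(cand, other_ok, logical(1), pos3 = pos, self = i)]
      if (!length(ok) && k > 0L && k < n_cod - 1L) {
        # middle codon: any non-stop codon will do if the preferred
        # (synonymous) set conflicts with an overlapping ORF
        fallback <- sample(setdiff(names(gc), .STOP_CODONS))
        if (any(fx <- fixed[pos])) {
          keep <- vapply(fallback, function(cd) {
            all(strsplit(cd, "")[[1]][fx] == chars[pos][fx])
          }, logical(1))
          fallback <- fallback[keep]
        }
        ok <- fallback[vapply(fallback, other_ok, logical(1), pos3 = pos,
                              self = i)]
      }
      cand <- ok
      if (!length(cand)) {
        .stopf(paste0("template '%s' rejected: overlap constraints force a ",
                      "stop (ORF %d, codon %d)"), template$name, i, k + 1L)
      }
      chars[pos] <- strsplit(cand[1], "")[[1]]
      fixed[pos] <- TRUE
      realised[k + 1L] <- cand[1]
    }
    proteins[i] <- paste(gc[realised[2:(n_cod - 1L)]], collapse = "")
  }

  # final verification of the construction guarantees
  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    cods <- substring(paste(chars[(s + 1L):e], collapse = ""),
                      seq(1L, e - s, 3L), seq(3L, e - s, 3L))
    if (!(cods[1] %in% .START_CODONS) ||
        !(cods[length(cods)] %in% .STOP_CODONS) ||
        any(cods[-length(cods)] %in% .STOP_CODONS)) {
      .stopf("template '%s' rejected: ORF %d could not be realised cleanly",
             template$name, i)
    }
  }

  features <- data.frame(
    genome = template$name, role = orfs$role, start = orfs$start,
    end = orfs$end, strand = "+", protein = proteins,
    stringsAsFactors = FALSE
  )
  list(name = template$name,
       sequence = paste(chars, collapse = ""),
       features = features)
}

#' Conserved-block coordinates for a simulated genome
#'
#' Maps the packaged domain-model motif intervals (padded by `pad` amino
#' acids) onto genome nucleotide coordinates for every annotated ORF with a
#' modelled role. These blocks emulate purifying selection: the community
#' generator restricts them to synonymous substitutions so that motif amino
#' acids stay recognisable across divergent phylotypes, as in real RdRp and
#' maturation genes.
#'
#' @param features feature data.frame from [simulateGenome()].
#' @param pad flanking amino acids added around each motif.
#' @return data.frame with `start`, `end` (genome nt, 0-based half-open),
#'   `orf_start` (frame anchor of the owning ORF).
#' @export
conservedBlocks <- function(features, pad = 8L) {
  defs <- .MODEL_DEFS
  out <- list()
  for (i in seq_len(nrow(features))) {
    role <- features$role[i]
    key <- if (role == "rdrp") "rdrp_ss" else role
    if (!key %in% names(defs) || !length(defs[[key]]$motifs)) next
    s <- features$start[i]; e <- features$end[i]
    n_aa <- (e - s) %/% 3L - 2L
    for (m in defs[[key]]$motifs) {
      a0 <- max(0L, m[1] - pad)
      b0 <- min(n_aa, m[2] + pad)
      if (b0 <= a0) next
      # +3 skips the start codon
      out[[length(out) + 1L]] <- data.frame(
        start = s + 3L + 3L * a0, end = s + 3L + 3L * b0, orf_start = s)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      orf_start = integer()))
  }
  do.call(rbind, out)
}

# Plant exactly `n_sub` substitutions at distinct positions.
# orf_aware: never touch start/stop codons, never create an in-frame stop in
# any covering ORF; inside conserved blocks only synonymous third-position
# changes are allowed.
.mutate_seq <- function(chars, n_sub, features = NULL, blocks = NULL,
                        orf_aware = FALSE) {
  L <- length(chars)
  bases <- c("A", "C", "G", "T")
  if (!orf_aware) {
    if (n_sub > L) .stopf("cannot plant %d substitutions in %d positions", n_sub, L)
    idx <- sample.int(L, n_sub)
    for (p in idx) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    return(chars)
  }
  stopifnot(!is.null(features))
  gc <- .genetic_code()
  in_block <- rep(FALSE, L)
  if (!is.null(blocks) && nrow(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      in_block[(blocks$start[i] + 1L):blocks$end[i]] <- TRUE
    }
  }
  protected <- rep(FALSE, L)  # start/stop codons
  for (i in seq_len(nrow(features))) {
    s <- features$start[i]; e <- features$end[i]
    protected[(s + 1L):(s + 3L)] <- TRUE
    protected[(e - 2L):e] <- TRUE
  }
  pool <- which(!protected)
  if (n_sub > length(pool)) {
    .stopf("cannot plant %d substitutions with only %d eligible positions",
           n_sub, length(pool))
  }
  allowed_alts <- function(p) {
    alts <- setdiff(bases, chars[p])
    for (i in seq_len(nrow(features))) {
      s <- features$start[i]; e <- features$end[i]
      if (p <= s || p > e) next
      k <- (p - s - 1L) %/% 3L
      cp <- s + 3L * k + (1:3)
      cod <- chars[cp]
      slot <- p - (s + 3L * k)
      keep <- vapply(alts, function(a) {
        cd <- cod; cd[slot] <- a
        cds <- paste(cd, collapse = "")
        if (cds %in% .STOP_CODONS) return(FALSE)
        if (in_block[p]) {
          if (slot != 3L) return(FALSE)
          gc[[cds]] == gc[[paste(cod, collapse = "")]]
        } else TRUE
      }, logical(1))
      alts <- alts[keep]
      if (!length(alts)) return(character())
    }
    alts
  }
  done <- 0L
  pool <- sample(pool)  # randomised scan order
  pi <- 1L
  while (done < n_sub) {
    if (pi > length(pool)) {
      .stopf("substitution target unreachable: only %d of %d placed", done, n_sub)
    }
    p <- pool[pi]; pi <- pi + 1L
    alts <- allowed_alts(p)
    if (!length(alts)) next
    chars[p] <- if (length(alts) == 1L) alts else sample(alts, 1L)
    done <- done + 1L
  }
  chars
}

#' Evolve a population of sequence variants
#'
#' Generates `n` descendants of `ancestor`, each carrying exactly
#' `round((1 - targetIdentity) * length)` substitutions at distinct
#' positions (Jukes-Cantor-style: the replacement base is uniform over the
#' three alternatives), so each variant's p-distance identity to the
#' ancestor equals the target. By default mutation is unconstrained -- ORFs
#' may be disrupted, as the discovery pipeline must tolerate. With
#' `orfAware = TRUE` (and `features` supplied) substitutions avoid start and
#' stop codons, never create in-frame stops, and are restricted to
#' synonymous changes inside `conservedBlocks`, emulating purifying
#' selection. With `indelRate > 0`, short (1-3 nt) indels are additionally
#' applied at approximately that per-base rate.
#'
#' @param ancestor nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @param targetIdentity fraction in (0, 1].
#' @param n number of variants.
#' @param seed RNG seed (`NULL`: continue caller's stream).
#' @param orfAware logical; respect ORF structure (default `FALSE`).
#' @param features,conservedBlocks ORF features and conserved-block table
#'   (see [simulateGenome()], [conservedBlocks()]); needed when
#'   `orfAware = TRUE`.
#' @param indelRate per-base indel rate (default 0: substitutions only).
#' @return character vector of `n` variant sequences.
#' @export
evolvePopulation <- function(ancestor, targetIdentity, n, seed = NULL,
                             orfAware = FALSE, features = NULL,
                             conservedBlocks = NULL, indelRate = 0) {
  if (!is.numeric(targetIdentity) || targetIdentity <= 0 || targetIdentity > 1) {
    .stopf("targetIdentity must lie in (0, 1], got %s", format(targetIdentity))
  }
  ancestor <- as.character(ancestor)
  run <- function() {
    chars <- strsplit(ancestor, "")[[1]]
    L <- length(chars)
    n_sub <- round((1 - targetIdentity) * L)
    vapply(seq_len(n), function(i) {
      v <- .mutate_seq(chars, n_sub, features, conservedBlocks, orfAware)
      if (indelRate > 0) {
        n_ind <- stats::rpois(1L, indelRate * L)
        for (j in seq_len(n_ind)) {
          p <- sample.int(length(v), 1L)
          w <- sample(1:3, 1L)
          if (stats::runif(1) < 0.5) {
            v <- append(v, sample(c("A", "C", "G", "T"), w, replace = TRUE),
                        after = p)
          } else {
            v <- v[-(p:min(length(v), p + w - 1L))]
          }
        }
      }
      paste(v, collapse = "")
    }, character(1))
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Simulate shotgun reads from a set of genomes
#'
#' Per-genome read counts are Poisson with mean
#' `coverage * length / readLength` (scaled by `abundances`); read start
#' positions are uniform, strands balanced, and substitution errors applied
#' per base at `errorRate` (uniform over the three alternative bases).
#' Background reads (uniform random sequence, truth label `"background"`)
#' are added so their expected share of the total read set equals
#' `backgroundFraction`.
#'
#' @param genomes named [Biostrings::DNAStringSet] or named character vector.
#' @param readLength read length, nt.
#' @param coverage mean per-genome fold coverage (> 0).
#' @param errorRate per-base substitution error rate.
#' @param backgroundFraction expected fraction of background reads in [0, 1).
#' @param seed RNG seed (`NULL`: continue caller's stream).
#' @param abundances optional per-genome relative abundance multipliers.
#' @return list with `reads` ([Biostrings::DNAStringSet]) and `truth`
#'   (data.frame: `read`, `source`, `start` (1-based), `strand`).
#' @export
shotgunReads <- function(genomes, readLength = 200L, coverage = 20,
                         errorRate = 0.01, backgroundFraction = 0,
                         seed = NULL, abundances = NULL) {
  if (coverage <= 0) .stopf("coverage must be positive")
  seqs <- .as_char_seqs(genomes)
  if (readLength > min(nchar(seqs))) {
    .stopf("readLength (%d) exceeds the shortest genome (%d nt)",
           readLength, min(nchar(seqs)))
  }
  if (is.null(abundances)) abundances <- rep(1, length(seqs))
  run <- function() {
    src <- character(); starts <- integer(); strands <- character()
    frag <- character()
    for (i in seq_along(seqs)) {
      L <- nchar(seqs[i])
      n_i <- stats::rpois(1L, coverage * L / readLength * abundances[i])
      if (n_i == 0L) next
      st <- sample.int(L - readLength + 1L, n_i, replace = TRUE)
      frag <- c(frag, substring(seqs[i], st, st + readLength - 1L))
      src <- c(src, rep(names(seqs)[i], n_i))
      starts <- c(starts, st)
      strands <- c(strands, sample(c("+", "-"), n_i, replace = TRUE))
    }
    n_phage <- length(frag)
    b <- backgroundFraction
    if (b > 0 && n_phage > 0) {
      n_bg <- stats::rpois(1L, n_phage * b / (1 - b))
      if (n_bg > 0) {
        bg <- vapply(seq_len(n_bg), function(j) {
          paste(sample(c("A", "C", "G", "T"), readLength, replace = TRUE),
                collapse = "")
        }, character(1))
        frag <- c(frag, bg)
        src <- c(src, rep("background", n_bg))
        starts <- c(starts, rep(NA_integer_, n_bg))
        strands <- c(strands, sample(c("+", "-"), n_bg, replace = TRUE))
      }
    }
    reads <- Biostrings::DNAStringSet(frag)
    minus <- strands == "-"
    if (any(minus)) {
      reads[minus] <- Biostrings::reverseComplement(reads[minus])
    }
    if (errorRate > 0 && length(reads)) {
      m <- as.matrix(reads)
      hit <- which(matrix(stats::runif(length(m)) < errorRate,
                          nrow(m), ncol(m)))
      if (length(hit)) {
        cur <- m[hit]
        bases <- c("A", "C", "G", "T")
        repl <- bases[(match(cur, bases) - 1L +
                       sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
        m[hit] <- repl
        reads <- Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
      }
    }
    ids <- sprintf("read_%06d", seq_along(reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read = ids, source = src, start = starts,
                            strand = strands, stringsAsFactors = FALSE))
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Parameters of a synthetic phage community
#'
#' Validated parameter set for [simulateCommunity()]. Identity targets are
#' expected pairwise identities among the emitted members: because variants
#' radiate from a common ancestor, the generator inverts the star-topology
#' relation `p = (1 - d)^2 + d^2 / 3` to find the per-branch divergence `d`
#' that realises the requested pairwise identity.
#'
#' @param nPhylotypes number of planted phylotypes (>= 1).
#' @param withinIdentity target pairwise nucleotide identity within a
#'   phylotype, in (0.70, 1].
#' @param betweenIdentity target pairwise nucleotide identity between
#'   phylotypes, in [0, 0.70). Targets below the uniform-substitution
#'   baseline of 0.25 saturate at maximal divergence.
#' @param variantsPerPhylotype variants per phylotype (>= 1).
#' @param readLength read length, nt.
#' @param coverage per-genome fold coverage.
#' @param errorRate per-base substitution error rate.
#' @param backgroundFraction expected background read fraction in [0, 1).
#' @param genomeLength genome length, nt (leviviral range 3.7-5.0 kb).
#' @param variantTruncMax maximal 5' truncation (nt) applied to variants
#'   after the first, so phylotype members differ in length as real partial
#'   genomes do.
#' @param orfAa optional compact ORF sizes, passed to [leviviralTemplate()].
#' @param seed integer RNG seed.
#' @return a validated list of class `community_spec`.
#' @export
communitySpec <- function(nPhylotypes = 12L, withinIdentity = 0.90,
                          betweenIdentity = 0.50, variantsPerPhylotype = 2L,
                          readLength = 200L, coverage = 20, errorRate = 0.01,
                          backgroundFraction = 0.10, genomeLength = 4000L,
                          variantTruncMax = 300L, orfAa = NULL, seed = 1L) {
  stopifnot(nPhylotypes >= 1L, variantsPerPhylotype >= 1L, coverage > 0)
  if (!(withinIdentity > 0.70 && withinIdentity <= 1)) {
    .stopf("withinIdentity must lie in (0.70, 1], got %s", withinIdentity)
  }
  if (!(betweenIdentity >= 0 && betweenIdentity < 0.70)) {
    .stopf("betweenIdentity must lie in [0, 0.70), got %s", betweenIdentity)
  }
  if (!(errorRate >= 0 && errorRate < 1) ||
      !(backgroundFraction >= 0 && backgroundFraction < 1)) {
    .stopf("errorRate and backgroundFraction must be fractions in [0, 1)")
  }
  structure(list(
    n_phylotypes = as.integer(nPhylotypes),
    within_identity = withinIdentity,
    between_identity = betweenIdentity,
    variants_per_phylotype = as.integer(variantsPerPhylotype),
    read_length = as.integer(readLength),
    coverage = coverage,
    error_rate = errorRate,
    background_fraction = backgroundFraction,
    genome_length = as.integer(genomeLength),
    variant_trunc_max = as.integer(variantTruncMax),
    orf_aa = orfAa,
    seed = as.integer(seed)
  ), class = "community_spec")
}

# star-topology inversion: per-branch divergence giving pairwise identity p
.divergence_for_pairwise <- function(p) {
  disc <- 1 - 4 * (1 - p) / 3
  if (disc <= 0) return(0.75)
  0.75 * (1 - sqrt(disc))
}

# Realized-identity guard bands around the 0.70 phylotype rule. The planted
# truth must satisfy the rule *as realized*, not merely in expectation:
# random substitution placement gives per-gene identities a binomial spread,
# so without a guard a community planted near the threshold would violate
# its own labels with high probability.
.PHYLOTYPE_RULE <- 0.70
.BETWEEN_GENE_CAP <- .PHYLOTYPE_RULE - 0.02
.WITHIN_GENE_FLOOR <- .PHYLOTYPE_RULE + 0.02

.gene_identity <- function(a, b, start, end) {
  va <- substring(a, start + 1L, end)
  vb <- substring(b, start + 1L, end)
  mean(strsplit(va, "")[[1]] == strsplit(vb, "")[[1]])
}

#' Simulate a synthetic phage community with ground truth
#'
#' Plants `nPhylotypes` phylotypes as star-radiations from a common
#' levivirus-like root genome, each with `variantsPerPhylotype` members, and
#' simulates a shotgun read set. Phylotype and variant divergence is
#' ORF-aware (no start/stop disruption; synonymous-only inside the
#' conserved motif blocks), emulating purifying selection so divergent
#' phylotypes keep intact, detectably homologous ORFs -- the situation the
#' discovery pipeline exists for. Because random substitution placement
#' spreads per-gene identities around their target, planted genomes are
#' additionally rejection-sampled so the *realized* RdRp and maturation
#' gene identities respect the 0.70 phylotype rule with a 0.02 guard band
#' (below it between phylotypes, above it within): the planted labels are
#' then consistent with the rule they are meant to test, by construction.
#' Variants after the first are 5'-truncated
#' by a random amount so the longest-representative rule has real work to
#' do. All randomness derives from `spec$seed`.
#'
#' @param spec a [communitySpec()].
#' @return a [PhageCommunity-class] object.
#' @export
simulateCommunity <- function(spec = communitySpec()) {
  stopifnot(inherits(spec, "community_spec"))
  .with_seed(spec$seed, {
    template <- leviviralTemplate(spec$genome_length, name = "root",
                                  orfAa = spec$orf_aa)
    root <- simulateGenome(template)
    blocks <- conservedBlocks(root$features)
    d_between <- .divergence_for_pairwise(spec$between_identity)
    d_within <- .divergence_for_pairwise(spec$within_identity)
    gene_regions <- root$features[root$features$role %in%
                                    c("maturation", "rdrp"), , drop = FALSE]
    gene_ids <- function(a, b) {
      vapply(seq_len(nrow(gene_regions)), function(i)
        .gene_identity(a, b, gene_regions$start[i], gene_regions$end[i]),
        numeric(1))
    }
    # plant ancestors whose realized per-gene identities stay below the
    # phylotype rule against every previously accepted ancestor
    ancestors <- character(spec$n_phylotypes)
    for (k in seq_len(spec$n_phylotypes)) {
      ok <- FALSE
      for (try in seq_len(50L)) {
        cand <- evolvePopulation(root$sequence, 1 - d_between, 1L,
                                 orfAware = TRUE, features = root$features,
                                 conservedBlocks = blocks)
        ok <- k == 1L || all(vapply(seq_len(k - 1L), function(j)
          all(gene_ids(cand, ancestors[j]) <= .BETWEEN_GENE_CAP),
          logical(1)))
        if (ok) break
      }
      if (!ok) {
        .stopf(paste0("could not plant phylotype %d below the %.2f identity ",
                      "rule; betweenIdentity = %.2f is too close to the ",
                      "threshold for this genome length"),
               k, .PHYLOTYPE_RULE, spec$between_identity)
      }
      ancestors[k] <- cand
    }
    genome_seqs <- character(); genome_names <- character()
    phylo_of <- character(); feat <- list()
    for (k in seq_len(spec$n_phylotypes)) {
      label <- sprintf("P%02d", k)
      vars <- NULL
      for (try in seq_len(50L)) {
        vars <- evolvePopulation(ancestors[k], 1 - d_within,
                                 spec$variants_per_phylotype, orfAware = TRUE,
                                 features = root$features,
                                 conservedBlocks = blocks)
        ok <- spec$variants_per_phylotype == 1L ||
          all(utils::combn(seq_along(vars), 2L, function(ij)
            all(gene_ids(vars[ij[1]], vars[ij[2]]) >= .WITHIN_GENE_FLOOR)))
        if (ok) break
      }
      if (!ok) {
        .stopf(paste0("could not keep phylotype %s variants above the %.2f ",
                      "identity rule; withinIdentity = %.2f is too close to ",
                      "the threshold"), label, .PHYLOTYPE_RULE,
               spec$within_identity)
      }
      for (j in seq_along(vars)) {
        nm <- sprintf("%s_v%d", label, j)
        sq <- vars[j]
        fts <- root$features
        fts$genome <- nm
        if (j > 1L && spec$variant_trunc_max > 0L) {
          tr <- sample.int(spec$variant_trunc_max + 1L, 1L) - 1L
          if (tr > 0L) {
            sq <- substring(sq, tr + 1L)
            fts <- fts[fts$end > tr, , drop = FALSE]
            fts$start <- pmax(0L, fts$start - tr)
            fts$end <- fts$end - tr
          }
        }
        genome_seqs <- c(genome_seqs, sq)
        genome_names <- c(genome_names, nm)
        phylo_of <- c(phylo_of, label)
        feat[[length(feat) + 1L]] <- fts
      }
    }
    genomes <- Biostrings::DNAStringSet(genome_seqs)
    names(genomes) <- genome_names
    sim <- shotgunReads(genomes, readLength = spec$read_length,
                        coverage = spec$coverage,
                        errorRate = spec$error_rate,
                        backgroundFraction = spec$background_fraction)
    truth <- sim$truth
    truth$phylotype <- ifelse(
      truth$source == "background", "background",
      phylo_of[match(truth$source, genome_names)])
    features <- do.call(rbind, feat)
    features$protein <- NULL  # ancestral coordinates only
    rownames(features) <- NULL
    methods::new("PhageCommunity",
                 genomes = genomes,
                 features = features,
                 reads = sim$reads,
                 readTruth = truth,
                 genomeTruth = data.frame(genome = genome_names,
                                          phylotype = phylo_of,
                                          length = nchar(genome_seqs),
                                          stringsAsFactors = FALSE),
                 spec = unclass(spec))
  })
}
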