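# Shared internals: alphabets, scoring matrices, seeded evaluation.

.pkg_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, expr) {
  if (!exists(key, envir = .pkg_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .pkg_cache)
  }
  get(key, envir = .pkg_cache, inherits = FALSE)
}

# BLOSUM62 as shipped with Biostrings (24-letter alphabet, integer mode).
.blosum62 <- function() {
  .cache_get("blosum62", {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    storage.mode(m) <- "integer"
    m
  })
}

.aa_alphabet <- function() rownames(.blosum62())

# Search variant of BLOSUM62: X (and any unknown residue mapped to X) scores
# as the minimum of the column over the 20 standard residues, so ambiguous
# translation products can only hurt an alignment and never seed it.
.search_matrix <- function() {
  .cache_get("search_matrix", {
    m <- .blosum62()
    xi <- match("X", rownames(m))
    colmin <- apply(m[1:20, , drop = FALSE], 2, min)
    rowmin <- apply(m[, 1:20, drop = FALSE], 1, min)
    m[xi, ] <- pmin(m[xi, ], colmin)
    m[, xi] <- pmin(m[, xi], rowmin)
    m[xi, xi] <- min(colmin)
    storage.mode(m) <- "integer"
    m
  })
}

.NT_ALPHABET <- c("A", "C", "G", "T", "N")

# BLASTn-like nucleotide scores; N is scored as a mismatch against everything
# (including N) and is excluded from identity denominators via the ambiguity
# flags.
.nt_matrix <- function(match = 2L, mismatch = -3L) {
  m <- matrix(mismatch, 5L, 5L, dimnames = list(.NT_ALPHABET, .NT_ALPHABET))
  diag(m) <- match
  m["N", "N"] <- mismatch
  storage.mode(m) <- "integer"
  m
}

# Encode a single sequence string to 0-based codes over `alphabet`;
# unknown characters map to `fallback` (e.g. "X" or "N").
.encode1 <- function(x, alphabet, fallback) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  i <- match(v, alphabet)
  i[is.na(i)] <- match(fallback, alphabet)
  as.integer(i - 1L)
}

.encode_aa <- function(x) .encode1(x, .aa_alphabet(), "X")
.encode_nt <- function(x) .encode1(x, .NT_ALPHABET, "N")

.as_char_seqs <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is(x, "XString")) {
    out <- as.character(x)
    names(out) <- "seq"
  } else {
    nm <- names(x)          # as.character() strips names
    out <- as.character(x)
    names(out) <- nm
  }
  if (length(out) && is.null(names(out))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  out
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Karlin-Altschul parameters used for translated-search statistics
# (BLOSUM62 with gap costs 11/1, as BLAST applies to gapped scores).
.KA_LAMBDA <- 0.267
.KA_K <- 0.041
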