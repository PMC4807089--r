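---
title: "Methods: discovering divergent RNA bacteriophages with rnaphage"
author: "rnaphage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering divergent RNA bacteriophages with rnaphage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the procedure

Known RNA bacteriophages — the ssRNA leviviruses
(maturation–coat–replicase genomes of roughly 3.7–4.3 kb) and the
segmented dsRNA cystoviruses — are represented by only a handful of
reference genomes. Their divergent relatives in metagenomes are
undetectable by nucleotide search; the workable signal is protein-level
homology concentrated in a few conserved regions, above all the palm
domain of the RNA-dependent RNA polymerase (RdRp) with its five conserved
motifs (A–E). `rnaphage` implements the resulting discovery chain as
composable, individually tested operations:

translated triage → assembly → length filter → ORF/domain annotation →
partial-genome classification → phylotype dereplication → species
delimitation → distance phylogenetics → prevalence/persistence summaries.

The package assumes single-end nucleotide reads (FASTA/FASTQ), protein
references for the homology search, and — for the prevalence module — a
specimen table with animal, site and categorical time-point labels.

# Stage models and parameters

## Translated triage

Each read is translated in six frames (`+1..+3` from the forward strand,
`-1..-3` from the reverse complement, trailing bases dropped; codons
containing `N` become `X`, stops `*`). Frames are screened for BLAST-style
neighbourhood words (word size 3; a word seeds when some query 3-mer
scores ≥ 13 against it under BLOSUM62) and seeded frame/query pairs are
aligned by full local Gotoh alignment (BLOSUM62; a gap of length *L* costs
11 + *L*). `X` scores as the worst entry of its column and never seeds, so
ambiguity can only hurt an alignment. E-values use the Karlin–Altschul
form `E = K · m · n · e^{−λS}` with the ungapped BLOSUM62 parameters
λ = 0.267 and K = 0.041 applied to gapped scores, as BLAST does; `m` is
the query length and `n` the total translated letters over all frames of
all reads. Agreement with any particular external search engine is not a
contract — ordering and thresholding behaviour is, and the test suite
checks the seeded search against exhaustive Smith–Waterman on the same
scoring system (the seeding threshold is far below the score any
E < 10⁻⁴ alignment needs, so seeding is a pure speed-up, never a filter).

A dataset is *selected* when at least 10 distinct reads (HSPs per read do
not accumulate) reach E strictly below 10⁻⁴. Both values are exposed
(`minReads`, `evalueCutoff`) with those defaults.

## Assembly

The greedy overlap assembler is intentionally small-scale — the selection
rules downstream, not the assembler, are the subject here. Reads join a
growing contig when they share a k-mer (k = 12, capped at the minimum
overlap) and overlap by ≥ 30 nt at ≤ 2 % mismatches, on either strand.
Among valid candidates the longest overlap wins (containments absorb
first), then the longest extension; ties break on the lexicographically
smallest oriented read sequence, and seeds are processed longest-first, so
the output is independent of input order up to contig naming. Placed reads
vote per position and the contig sequence is the majority consensus, which
at ≥ 15× coverage drives the consensus error toward zero even with 1 %
read errors. Unmerged reads emerge as singleton contigs and are removed by
the strict `> 750 nt` length rule.

## Annotation and the partial-genome rule

ORFs are predicted in all six frames with bacterial start codons
(ATG/GTG/TTG; leviviral hosts are bacteria), minimum protein length 50 aa.
Within a frame, each stop closes a segment and the segment's ORF runs from
its first start codon to the stop; segments touching a contig edge
additionally yield edge-partial ORFs (5'-partials need no start codon),
because real partial genomes truncate genes. Coordinates are 0-based
half-open internally and 1-based inclusive in GFF3/GenBank-style output.

Domain assignment replaces external conserved-domain and structure
services with packaged position-specific models scored by best ungapped
local segment under BLOSUM62 against a family consensus. Thresholds are
calibrated so that every packaged reference protein passes on its own
family model while composition-shuffled proteins fail in ≥ 95 % of
shuffles: a call requires a raw score of at least
`max(60, 0.04 × self-score)`. The ssRNA RdRp model carries the five palm
motif intervals; a motif counts as covered when its sub-model scores
≥ 60 % of its self-score anywhere in the protein, and `palmComplete()`
demands all five. Ungapped scanning is adequate here because the synthetic
data are substitution-only; on real data with indels it understates scores
(a known limitation, below).

A contig becomes a *partial genome* when it exceeds 750 nt and at least
one translated frame carries a domain call.

## Identity conventions (two, deliberately)

`globalAlignIdentity()` performs Needleman–Wunsch with affine gaps
(nucleotide +2/−3 with gap costs 5 + 2*L*; protein BLOSUM62 with 11 +
*L*) and reports two identities:

* **p-distance identity** — identical columns over columns where both
  sequences place an unambiguous residue (pairwise gap deletion). This is
  the protein convention used for species delimitation.
* **span identity** — identical columns over *all* columns between the
  first and last aligned residue pair: internal gaps count against
  identity, terminal overhangs do not. This matches the behaviour of
  local-alignment (BLASTn-style) identities the 70 % phylotype rule was
  formulated with.

The distinction matters. Under pure gap deletion, a truncated gene aligned
to a complete one silently drops its unmatched tail from the denominator,
so a pair planted well below the 70 % rule can measure above it and merge
distinct phylotypes. `clusterPhylotypes()` therefore uses span identity
by default (`identity = "pdist"` restores the gap-deleted
flavour), and the pipeline additionally refuses to phylotype on gene ORFs
covering less than 75 % of their domain model (`minGeneFrac`): a
conserved-block fragment aligns at inflated identity to every family
member and would transitively chain unrelated clusters. Contigs left
without a qualifying gene are excluded from dereplication with a warning.

Phylotype linkage is single linkage (the stated rule is a pairwise
relation closed transitively; no other linkage is implied), with a strict
`> 0.70` threshold; species cutoffs are non-strict (`≥`), both read
directly off the wording of the respective rules. Representative choice is
the longest member, ties broken by lexicographically smallest identifier.
Because RNA viruses encode a single RdRp, the pipeline also reports the
conservative phylotype count restricted to clusters containing a
qualifying RdRp gene — maturation-only clusters may be 5' halves of
genomes counted already.

## Phylogenetics

`trimBlocks()` implements the classic conserved-block trimming semantics:
columns are classified by the occupancy of their most frequent residue
(conserved / highly conserved thresholds default to `n/2 + 1` and
`0.85 n`), runs of non-conserved columns longer than 20 are rejected,
blocks are trimmed inward to flank-level columns, and blocks shorter than
4 columns are dropped; `gapPolicy = "all"` leaves gap columns eligible.
Parameter semantics, not bit-compatibility with the original binary, are
the contract. Distances are p-distance (amino acid) or Kimura
2-parameter, `d = −½ ln((1 − 2P − Q)√(1 − 2Q))` with transitions `P` and
transversions `Q` over pairwise-complete sites; saturated pairs raise an
error rather than returning a fabricated distance. Trees are Saitou–Nei
neighbour joining (negative branches clamped to zero) with column
bootstrap; support values are bipartition percentages over successful
replicates, and a fixed seed reproduces them exactly. Maximum-likelihood
inference is intentionally out of scope: topology-level agreement is the
contract, and the additivity property (exact recovery of generating
topologies from additive matrices) is property-tested.

The pipeline builds its representatives' tree on the full RdRp protein
alignment rather than the trimmed one: in the synthetic world the strongly
conserved columns that survive trimming are exactly the ones carrying no
between-phylotype signal, so trimming is exposed as an operation but not
wired into the default tree.

## Prevalence

Presence is "at least one sequence": a phylotype × specimen cell is true
iff at least one detection links them, with a configurable minimum read
count for metagenomic evidence; RT-PCR and metagenomic evidence can be
kept as separate matrices by filtering on the evidence column. Persistence
counts, per phylotype, animals detected at ≥ 1 and at ≥ 2 distinct
categorical time points. The amplicon geography check declares sites
distinct iff the minimum within-site identity exceeds the maximum
between-site identity; single-sequence sites are excluded from the
within-site mean with a warning.

# The synthetic community generator

`simulateCommunity()` emulates the statistical structure the analysis
assumes: `K` phylotypes radiating from a common levivirus-like root
genome (default 4.0 kb: 5' UTR, maturation 1,272 nt — matching the
reference average of ~1.27 kb — coat 390 nt, RdRp 1,632 nt), each with
`variantsPerPhylotype` members, shotgun reads with Poisson per-genome
coverage, uniform positions, balanced strands, uniform substitution
errors, and uniform-random background reads.

Design choices that deserve justification:

* **Identity targets are pairwise.** Members radiate from a common
  ancestor, so the generator inverts the star relation
  `p = (1 − d)² + d²/3` to find the per-branch divergence `d` realising a
  requested pairwise identity `p`. Targets below the uniform-substitution
  baseline of 0.25 saturate.
* **Purifying selection is emulated.** Community divergence avoids start
  and stop codons, never creates in-frame stops, and restricts the
  conserved motif blocks (motifs ± 8 codons) to synonymous third-position
  changes. Without this, 50 % nucleotide divergence would destroy every
  ORF and all translated-search signal — precisely unlike the real,
  selectable phages the pipeline exists to find. Plain
  `evolvePopulation()` keeps the unconstrained uniform model by default
  (`orfAware = FALSE`), so downstream code is still exercised against
  broken ORFs; an optional indel rate adds short (1–3 nt) indels.
* **Realized identities are guarded.** Random substitution placement
  spreads per-gene identities by roughly ±1.5 percentage points, so a
  community planted near the 70 % rule would violate its own labels with
  high probability at realistic `K`. Planted genomes are
  rejection-sampled until realized RdRp and maturation identities sit
  below 0.68 between phylotypes and above 0.72 within them — the planted
  labels are then consistent with the rule they exist to test, by
  construction.
* **Variants differ in length.** Variants after the first are 5'-truncated
  by up to 300 nt, so the longest-representative rule has real work to do
  and downstream code sees partial genes.
* **Defaults as study conditions.** 12 phylotypes, within-identity 0.90
  (the 85–97 % range seen among real phylotype variants), between-identity
  0.50, 2 variants per phylotype, 200-nt reads at 20× per genome with 1 %
  substitution error and 10 % background. Read length and coverage are
  fixtures, not claims about any particular platform.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: indel evolution and alignment-gap handling
around the identity thresholds; chimeric reads and amplification bias;
platform-specific error and quality profiles; dsRNA segment co-occurrence
beyond emitting segments as separate sequences; host assignment. The
packaged reference proteins are a synthetic stand-in set (generated
deterministically by `inst/scripts/make_synthetic_references.R`), so
absolute domain scores are not comparable to scores against the real
reference phage proteins, only the decision structure is.

# Numerical and degenerate-input choices

* Exact substitution counts: `evolvePopulation()` plants
  `round((1 − t)·L)` substitutions at distinct positions, so identity to
  the ancestor is exact, and the ±0.02 contract is met trivially.
* Alignment tracebacks prefer diagonal, then vertical, then horizontal
  moves; local-alignment ties resolve to the smallest end cell —
  determinism everywhere.
* `N`/`X` are scored as mismatches (worst column score in the search
  matrix) and excluded from identity denominators.
* Saturated K2P pairs, empty alignments after trimming, genomes lacking
  both phylotyping genes, detections referencing unknown specimens, and
  sub-three-taxon trees all raise errors or warnings rather than silent
  values.
* Templates whose declared ORF overlaps are unrealisable (a shared codon
  forced to a stop in the partner frame after retries) are rejected with a
  diagnostic naming the ORF and codon.

# Problem sizes

The shipped tests run entirely on synthetic data: the clustering grid uses
compact 2.6-kb genomes (RdRp 903 nt, maturation 603 nt) over
K ∈ {3, 12, 25}, the aligner oracle 200 random pairs up to 60 residues,
the search-completeness check 50 reads × 5 queries, the ORF oracle 100
random 1–3 kb contigs, and the end-to-end check the full default community
(~10,500 reads). These sizes were chosen as the smallest at which the
statistical properties under test are unambiguous.

# Known limitations

Ungapped domain scanning and substitution-only simulation understate the
difficulty of real, indel-rich divergence; the greedy assembler is not a
production assembler and will fragment low-coverage genomes (the
conservative RdRp-based phylotype count exists for exactly that case); the
E-value calibration follows BLAST's pragmatic reuse of ungapped
Karlin–Altschul parameters and is not an exact tail probability; manual
alignment curation steps in the original workflow are inherently
irreproducible and are not emulated.
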