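#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <array>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Toy greedy overlap assembler with consensus voting.
//
// Reads are placed onto a growing contig whenever they share a k-mer with a
// contig end and their suffix-prefix overlap (either strand) is at least
// min_overlap with a mismatch fraction <= max_mismatch. The candidate with
// the longest extension wins; ties break on the lexicographically smallest
// oriented read sequence, then forward strand. Seeds are processed longest
// read first (ties: lexicographically smallest), so the result does not
// depend on input order. Contained reads are absorbed and vote in the
// consensus. Final contigs are reported on their canonical strand (the
// lexicographically smaller of sequence / reverse complement).

typedef std::array<int, 4> Votes;

static inline uint8_t comp(uint8_t b) { return b < 4 ? 3 - b : b; }

static std::vector<uint8_t> revcomp(const std::vector<uint8_t>& s) {
  std::vector<uint8_t> r(s.size());
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp(s[i]);
  return r;
}

static inline uint8_t code_of(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

struct Entry { int32_t read; int32_t pos; uint8_t strand; };

struct Cand {
  int read; uint8_t strand; long offset; long ov; long ext;
};

class Contig {
 public:
  std::deque<Votes> votes;
  std::deque<uint8_t> cons;
  long size() const { return (long)cons.size(); }
  void call(long i) {
    const Votes& v = votes[i];
    int best = 0;
    for (int b = 1; b < 4; ++b) if (v[b] > v[best]) best = b;
    cons[i] = (uint8_t)best;
  }
  void add_read(const std::vector<uint8_t>& s, long offset) {
    if (offset < 0) {
      for (long i = 0; i < -offset; ++i) {
        votes.push_front(Votes{0, 0, 0, 0});
        cons.push_front(0);
      }
      offset = 0;
    }
    while ((long)cons.size() < offset + (long)s.size()) {
      votes.push_back(Votes{0, 0, 0, 0});
      cons.push_back(0);
    }
    for (size_t i = 0; i < s.size(); ++i) {
      if (s[i] < 4) votes[offset + i][s[i]]++;
      call(offset + i);
    }
  }
  int mismatches(const std::vector<uint8_t>& s, long offset, long ov_start,
                 long ov_end) const {
    int mm = 0;
    for (long p = ov_start; p < ov_end; ++p) {
      const uint8_t rb = s[p - offset];
      if (rb >= 4 || rb != cons[p]) ++mm;
    }
    return mm;
  }
};

// [[Rcpp::export]]
List cpp_greedy_assemble(CharacterVector reads, int min_overlap,
                         double max_mismatch, int kmer) {
  const int n = reads.size();
  std::vector<std::vector<uint8_t> > fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    std::vector<uint8_t> v;
    for (const char* p = s; *p; ++p) v.push_back(code_of(*p));
    fwd[i] = v;
    rev[i] = revcomp(v);
  }
  const int k = kmer;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // global k-mer index over both strands of every read
  std::unordered_map<uint64_t, std::vector<Entry> > index;
  index.reserve((size_t)n * 64);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < 2; ++s) {
      const std::vector<uint8_t>& v = s ? rev[i] : fwd[i];
      if ((int)v.size() < k) continue;
      uint64_t h = 0; int run = 0;
      for (size_t p = 0; p < v.size(); ++p) {
        if (v[p] >= 4) { run = 0; h = 0; continue; }
        h = ((h << 2) | v[p]) & mask;
        if (++run >= k)
          index[h].push_back(Entry{i, (int32_t)(p - k + 1), (uint8_t)s});
      }
    }
  }

  // seed order: longest first, then lexicographically smallest sequence
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (fwd[a].size() != fwd[b].size()) return fwd[a].size() > fwd[b].size();
    if (fwd[a] != fwd[b]) return fwd[a] < fwd[b];
    return a < b;
  });

  std::vector<bool> used(n, false);
  std::vector<int> read2contig(n, NA_INTEGER);
  std::vector<std::string> contig_seqs;
  std::vector<int> contig_nreads;
  size_t maxlen = 0;
  for (int i = 0; i < n; ++i) maxlen = std::max(maxlen, fwd[i].size());

  auto gather = [&](const Contig& ctg, long from, long to,
                    std::vector<Cand>& out) {
    from = std::max(0L, from);
    to = std::min(ctg.size(), to);
    if (to - from < k) return;
    uint64_t h = 0; int run = 0;
    for (long p = from; p < to; ++p) {
      const uint8_t b = ctg.cons[p];
      if (b >= 4) { run = 0; h = 0; continue; }
      h = ((h << 2) | b) & mask;
      if (++run < k) continue;
      auto it = index.find(h);
      if (it == index.end()) continue;
      for (const Entry& e : it->second) {
        if (used[e.read]) continue;
        out.push_back(Cand{e.read, e.strand, (p - k + 1) - e.pos, 0, 0});
      }
    }
    // deduplicate (read, strand, offset) triples
    std::sort(out.begin(), out.end(), [](const Cand& a, const Cand& b) {
      if (a.read != b.read) return a.read < b.read;
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.offset < b.offset;
    });
    out.erase(std::unique(out.begin(), out.end(),
                          [](const Cand& a, const Cand& b) {
                            return a.read == b.read && a.strand == b.strand &&
                                   a.offset == b.offset;
                          }),
              out.end());
  };

  auto validate = [&](const Contig& ctg, Cand& c) -> bool {
    const std::vector<uint8_t>& s = c.strand ? rev[c.read] : fwd[c.read];
    const long L = (long)s.size();
    const long ov_start = std::max(0L, c.offset);
    const long ov_end = std::min(ctg.size(), c.offset + L);
    const long ov = ov_end - ov_start;
    if (ov < min_overlap) return false;
    const int mm = ctg.mismatches(s, c.offset, ov_start, ov_end);
    if ((double)mm > max_mismatch * (double)ov + 1e-9) return false;
    c.ov = ov;
    c.ext = std::max(0L, c.offset + L - ctg.size()) + std::max(0L, -c.offset);
    return true;
  };

  // deterministic preference among valid candidates: longest overlap first
  // (containments absorb before extensions), then longest extension
  auto better = [&](const Cand& a, const Cand& b) -> bool {
    if (a.ov != b.ov) return a.ov > b.ov;
    if (a.ext != b.ext) return a.ext > b.ext;
    const std::vector<uint8_t>& sa = a.strand ? rev[a.read] : fwd[a.read];
    const std::vector<uint8_t>& sb = b.strand ? rev[b.read] : fwd[b.read];
    if (sa != sb) return sa < sb;
    if (a.strand != b.strand) return a.strand < b.strand;
    if (a.read != b.read) return a.read < b.read;
    return a.offset < b.offset;
  };

  for (int oi = 0; oi < n; ++oi) {
    const int seed = order[oi];
    if (used[seed]) continue;
    Contig ctg;
    ctg.add_read(fwd[seed], 0);
    used[seed] = true;
    std::vector<int> members(1, seed);

    bool progress = true;
    while (progress) {
      progress = false;
      std::vector<Cand> cands;
      gather(ctg, ctg.size() - (long)maxlen - k, ctg.size(), cands);
      gather(ctg, 0, (long)maxlen + k, cands);
      bool have = false;
      Cand best{};
      for (Cand& c : cands) {
        if (!validate(ctg, c)) continue;
        if (!have || better(c, best)) { best = c; have = true; }
      }
      if (have && best.ext > 0) {
        const std::vector<uint8_t>& s =
            best.strand ? rev[best.read] : fwd[best.read];
        ctg.add_read(s, best.offset);
        used[best.read] = true;
        members.push_back(best.read);
        progress = true;
      } else if (have) {
        // containment at the ends: absorb and keep looking
        const std::vector<uint8_t>& s =
            best.strand ? rev[best.read] : fwd[best.read];
        ctg.add_read(s, best.offset);
        used[best.read] = true;
        members.push_back(best.read);
        progress = true;
      }
    }
    // interior containment sweep: gather once per pass, place every
    // candidate that validates, in deterministic preference order
    bool swept = true;
    while (swept) {
      swept = false;
      std::vector<Cand> cands;
      gather(ctg, 0, ctg.size(), cands);
      std::vector<Cand> valid;
      for (Cand& c : cands) {
        if (validate(ctg, c)) valid.push_back(c);
      }
      std::sort(valid.begin(), valid.end(), better);
      for (Cand& c : valid) {
        if (used[c.read]) continue;
        if (!validate(ctg, c)) continue;  // consensus may have shifted
        const std::vector<uint8_t>& s =
            c.strand ? rev[c.read] : fwd[c.read];
        ctg.add_read(s, c.offset);
        used[c.read] = true;
        members.push_back(c.read);
        swept = true;
      }
    }

    // canonical strand
    std::vector<uint8_t> seq(ctg.cons.begin(), ctg.cons.end());
    std::vector<uint8_t> rc = revcomp(seq);
    const std::vector<uint8_t>& out = (rc < seq) ? rc : seq;
    static const char* B = "ACGTN";
    std::string str(out.size(), 'N');
    for (size_t p = 0; p < out.size(); ++p) str[p] = B[out[p]];
    contig_seqs.push_back(str);
    contig_nreads.push_back((int)members.size());
    for (int r : members) read2contig[r] = (int)contig_seqs.size();
  }

  return List::create(_["contigs"] = wrap(contig_seqs),
                      _["n_reads"] = wrap(contig_nreads),
                      _["read2contig"] = wrap(read2contig));
}
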