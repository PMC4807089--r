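#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels (Gotoh). Sequences arrive as 0-based
// integer code vectors indexing rows/columns of the substitution matrix.
// A gap of length L costs gap_open + L * gap_ext (NCBI convention: the first
// gapped position pays gap_open + gap_ext).

static const int NEG = INT_MIN / 4;

static inline int idx(int i, int j, int ncol) { return i * ncol + j; }

// ---------------------------------------------------------------------------
// Global alignment (Needleman-Wunsch/Gotoh) with traceback statistics.
// Identity bookkeeping uses pairwise gap deletion: only columns where both
// sequences place a residue count as aligned positions; columns containing an
// ambiguous residue (is_ambig_* true) are excluded from that denominator.
// Traceback tie preference: diagonal, then vertical (gap in b), then
// horizontal (gap in a) -- fixed so results are deterministic.
// [[Rcpp::export]]
List cpp_global_align(IntegerVector a, IntegerVector b, IntegerMatrix submat,
                      int gap_open, int gap_ext,
                      LogicalVector a_ambig, LogicalVector b_ambig) {
  const int n = a.size(), m = b.size();
  const int ncol = m + 1;
  std::vector<int> H((n + 1) * ncol, NEG), E((n + 1) * ncol, NEG),
      F((n + 1) * ncol, NEG);
  H[idx(0, 0, ncol)] = 0;
  for (int j = 1; j <= m; ++j) {
    E[idx(0, j, ncol)] = -(gap_open + gap_ext * j);
    H[idx(0, j, ncol)] = E[idx(0, j, ncol)];
  }
  for (int i = 1; i <= n; ++i) {
    F[idx(i, 0, ncol)] = -(gap_open + gap_ext * i);
    H[idx(i, 0, ncol)] = F[idx(i, 0, ncol)];
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int e = std::max(H[idx(i, j - 1, ncol)] - gap_open - gap_ext,
                             E[idx(i, j - 1, ncol)] - gap_ext);
      const int f = std::max(H[idx(i - 1, j, ncol)] - gap_open - gap_ext,
                             F[idx(i - 1, j, ncol)] - gap_ext);
      const int d = H[idx(i - 1, j - 1, ncol)] + submat(a[i - 1], b[j - 1]);
      E[idx(i, j, ncol)] = e;
      F[idx(i, j, ncol)] = f;
      H[idx(i, j, ncol)] = std::max(d, std::max(e, f));
    }
  }
  // traceback; column types collected (reverse order): 1 residue-residue,
  // 0 gap column
  int i = n, j = m;
  int state = 0;  // 0 = H, 1 = F (vertical), 2 = E (horizontal)
  long identical = 0, aligned = 0;
  std::vector<char> cols;
  cols.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i > 0 && j > 0 &&
          H[idx(i, j, ncol)] ==
              H[idx(i - 1, j - 1, ncol)] + submat(a[i - 1], b[j - 1])) {
        const bool amb = a_ambig[i - 1] || b_ambig[j - 1];
        if (!amb) {
          ++aligned;
          if (a[i - 1] == b[j - 1]) ++identical;
        }
        cols.push_back(1);
        --i; --j;
      } else if (i > 0 && (j == 0 || H[idx(i, j, ncol)] == F[idx(i, j, ncol)])) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // vertical: consume a[i-1] against a gap
      if (!(F[idx(i, j, ncol)] ==
            F[idx(i - 1, j, ncol)] - gap_ext) ||
          i == 1) {
        state = 0;
      }
      cols.push_back(0);
      --i;
    } else {
      if (!(E[idx(i, j, ncol)] ==
            E[idx(i, j - 1, ncol)] - gap_ext) ||
          j == 1) {
        state = 0;
      }
      cols.push_back(0);
      --j;
    }
  }
  // span = columns between the first and last residue-residue column
  // (terminal gap overhangs excluded)
  long first = -1, last = -1;
  for (long c = 0; c < (long)cols.size(); ++c) {
    if (cols[c]) { if (last < 0) last = c; first = c; }
  }
  const long span = (first >= 0) ? (first - last + 1) : 0;
  return List::create(_["score"] = H[idx(n, m, ncol)],
                      _["identical"] = (double)identical,
                      _["aligned"] = (double)aligned,
                      _["columns"] = (double)cols.size(),
                      _["span_columns"] = (double)span);
}

// ---------------------------------------------------------------------------
// Local alignment (Smith-Waterman/Gotoh) returning the single best-scoring
// segment pair with its coordinates (0-based, half-open). Ties on the best
// score resolve to the smallest (i, j) end cell.
// [[Rcpp::export]]
List cpp_local_align(IntegerVector a, IntegerVector b, IntegerMatrix submat,
                     int gap_open, int gap_ext) {
  const int n = a.size(), m = b.size();
  const int ncol = m + 1;
  std::vector<int> H((n + 1) * ncol, 0), E((n + 1) * ncol, NEG),
      F((n + 1) * ncol, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int e = std::max(H[idx(i, j - 1, ncol)] - gap_open - gap_ext,
                             E[idx(i, j - 1, ncol)] - gap_ext);
      const int f = std::max(H[idx(i - 1, j, ncol)] - gap_open - gap_ext,
                             F[idx(i - 1, j, ncol)] - gap_ext);
      const int d = H[idx(i - 1, j - 1, ncol)] + submat(a[i - 1], b[j - 1]);
      E[idx(i, j, ncol)] = e;
      F[idx(i, j, ncol)] = f;
      int h = std::max(0, std::max(d, std::max(e, f)));
      H[idx(i, j, ncol)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj) to the first zero H cell
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H[idx(i, j, ncol)] == 0) break;
      if (H[idx(i, j, ncol)] ==
          H[idx(i - 1, j - 1, ncol)] + submat(a[i - 1], b[j - 1])) {
        --i; --j;
      } else if (H[idx(i, j, ncol)] == F[idx(i, j, ncol)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      if (!(F[idx(i, j, ncol)] == F[idx(i - 1, j, ncol)] - gap_ext) || i == 1)
        state = 0;
      --i;
    } else {
      if (!(E[idx(i, j, ncol)] == E[idx(i, j - 1, ncol)] - gap_ext) || j == 1)
        state = 0;
      --j;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj);
}

// ---------------------------------------------------------------------------
// Best ungapped local segment (per-diagonal Kadane scan), used for
// position-specific motif-model scanning.
// [[Rcpp::export]]
List cpp_ungapped_local(IntegerVector a, IntegerVector b, IntegerMatrix submat) {
  const int n = a.size(), m = b.size();
  int best = 0, ba_s = 0, ba_e = 0, bb_s = 0, bb_e = 0;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    // cells (i, j) with j - i == d
    int i0 = d >= 0 ? 0 : -d;
    int cur = 0, cs = i0;
    for (int i = i0; i < n && i + d < m; ++i) {
      cur += submat(a[i], b[i + d]);
      if (cur <= 0) { cur = 0; cs = i + 1; continue; }
      if (cur > best) {
        best = cur;
        ba_s = cs; ba_e = i + 1;
        bb_s = cs + d; bb_e = i + d + 1;
      }
    }
  }
  return List::create(_["score"] = best, _["a_start"] = ba_s, _["a_end"] = ba_e,
                      _["b_start"] = bb_s, _["b_end"] = bb_e);
}

// ---------------------------------------------------------------------------
// Neighbourhood-word seeding support. Builds, over the 20^3 standard-residue
// words, a logical table marking for each query whether a word scores at
// least `word_threshold` against some 3-mer of the query (BLAST-style T
// parameter). Codes >= 20 (X, ambiguity, stop) never seed.
// [[Rcpp::export]]
LogicalMatrix cpp_word_lookup(List queries, IntegerMatrix submat,
                              int word_threshold) {
  const int nq = queries.size();
  const int NW = 20 * 20 * 20;
  LogicalMatrix out(NW, nq);
  for (int q = 0; q < nq; ++q) {
    IntegerVector v = queries[q];
    const int L = v.size();
    for (int p = 0; p + 2 < L; ++p) {
      const int x1 = v[p], x2 = v[p + 1], x3 = v[p + 2];
      if (x1 >= 20 || x2 >= 20 || x3 >= 20) continue;
      for (int a = 0; a < 20; ++a) {
        const int s1 = submat(a, x1);
        if (s1 + 2 * 11 < word_threshold) continue;  // 11 = max BLOSUM62 entry
        for (int b = 0; b < 20; ++b) {
          const int s2 = s1 + submat(b, x2);
          if (s2 + 11 < word_threshold) continue;
          for (int c = 0; c < 20; ++c) {
            if (s2 + submat(c, x3) >= word_threshold)
              out(a * 400 + b * 20 + c, q) = true;
          }
        }
      }
    }
  }
  return out;
}

// score-only local Gotoh with rolling rows and a caller-provided workspace;
// identical scoring scheme to cpp_local_align
static int sw_score_only(const int* a, int n, const int* b, int m,
                         const int* sub, int nrow_sub, int gap_open,
                         int gap_ext, std::vector<int>& H,
                         std::vector<int>& E) {
  H.assign(m + 1, 0);
  E.assign(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0;       // H[i-1][j-1]
    int f = NEG;        // F[i][j] for current row
    int hprev = 0;      // H[i][j-1]
    const int* srow = sub + a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int e = std::max(hprev - gap_open - gap_ext, E[j] - gap_ext);
      f = std::max(H[j] - gap_open - gap_ext, f - gap_ext);
      int h = diag + srow[(size_t)b[j - 1] * nrow_sub];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      E[j] = e;
      hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Seeded translated search. read_frames: list (per read) of 6 integer-coded
// translated frames. For each read frame, queries seeded by a shared
// neighbourhood word are scanned with a score-only local Gotoh pass; hits
// passing the E-value cutoff are re-aligned with traceback for coordinates.
// Karlin-Altschul statistics: bits = (lambda * S - ln K) / ln 2,
// E = m * n_db * 2^-bits. If evalue_max is finite, only hits with E
// strictly below it are kept.
// [[Rcpp::export]]
DataFrame cpp_translated_search(List read_frames, List queries,
                                IntegerMatrix submat, int gap_open,
                                int gap_ext, LogicalMatrix lookup,
                                double lambda, double logK, double db_letters,
                                double evalue_max) {
  const int nq = queries.size();
  const int nrow_sub = submat.nrow();
  std::vector<int> subflat(submat.begin(), submat.end());
  std::vector<std::vector<int> > qcodes(nq);
  std::vector<int> qlen(nq);
  for (int q = 0; q < nq; ++q) {
    IntegerVector qv = queries[q];
    qcodes[q].assign(qv.begin(), qv.end());
    qlen[q] = qv.size();
  }
  std::vector<int> o_read, o_frame, o_query, o_score;
  std::vector<double> o_bits, o_eval;
  std::vector<int> o_rs, o_re, o_qs, o_qe;
  const int nr = read_frames.size();
  std::vector<bool> cand(nq);
  std::vector<int> wsH, wsE, vbuf;
  for (int r = 0; r < nr; ++r) {
    List frames = read_frames[r];
    for (int f = 0; f < 6; ++f) {
      IntegerVector v = frames[f];
      const int L = v.size();
      if (L < 3) continue;
      std::fill(cand.begin(), cand.end(), false);
      bool any = false;
      for (int p = 0; p + 2 < L; ++p) {
        const int x1 = v[p], x2 = v[p + 1], x3 = v[p + 2];
        if (x1 >= 20 || x2 >= 20 || x3 >= 20) continue;
        const int w = x1 * 400 + x2 * 20 + x3;
        for (int q = 0; q < nq; ++q) {
          if (!cand[q] && lookup(w, q)) { cand[q] = true; any = true; }
        }
      }
      if (!any) continue;
      vbuf.assign(v.begin(), v.end());
      for (int q = 0; q < nq; ++q) {
        if (!cand[q]) continue;
        const int S = sw_score_only(vbuf.data(), L, qcodes[q].data(), qlen[q],
                                    subflat.data(), nrow_sub, gap_open,
                                    gap_ext, wsH, wsE);
        if (S <= 0) continue;
        const double bits = (lambda * S - logK) / std::log(2.0);
        const double E =
            (double)qlen[q] * db_letters * std::pow(2.0, -bits);
        if (R_finite(evalue_max) && !(E < evalue_max)) continue;
        List al = cpp_local_align(v, queries[q], submat, gap_open, gap_ext);
        o_read.push_back(r + 1);
        o_frame.push_back(f + 1);
        o_query.push_back(q + 1);
        o_score.push_back(S);
        o_bits.push_back(bits);
        o_eval.push_back(E);
        o_rs.push_back(as<int>(al["a_start"]));
        o_re.push_back(as<int>(al["a_end"]));
        o_qs.push_back(as<int>(al["b_start"]));
        o_qe.push_back(as<int>(al["b_end"]));
      }
    }
  }
  return DataFrame::create(
      _["read"] = o_read, _["frame"] = o_frame, _["query"] = o_query,
      _["score"] = o_score, _["bits"] = o_bits, _["evalue"] = o_eval,
      _["read_start"] = o_rs, _["read_end"] = o_re, _["query_start"] = o_qs,
      _["query_end"] = o_qe);
}
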