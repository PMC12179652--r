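// Tandem-array detection core.
//
// detect_tandem_repeats() scores a candidate array as the local alignment of
// the sequence against a cyclically tiled consensus pattern:
//     score = match * (#matched) - mismatch * (#mismatched) - indel * (#indels)
// A perfect array of length L therefore scores match * L.  The wraparound
// dynamic programme below (after the classic TRF formulation) aligns the
// sequence against the pattern read modulo its period, so arrays may start
// and end at any phase and may contain fractional copies.
//
// A separate, deliberately naive oracle (oracle_best_score_cpp) maximises the
// same score by plain Smith-Waterman against explicitly tiled patterns; it is
// kept free of the wraparound machinery so the two paths can check each other.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_set>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int code_of(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N / IUPAC ambiguity: mismatch against every base
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

struct Wt { int match, mismatch, indel; };

struct AlnResult {
  int score = 0;
  int start = 0, end = 0;  // sequence coords, 0-based half-open
  int n_match = 0, n_mismatch = 0, n_indel = 0;
  int first_col = 0;       // pattern column of the first aligned base
  std::string consensus;   // column majority over the traceback
  bool ok = false;
};

struct Ws {
  std::vector<int> H;
  std::vector<int8_t> D;
  std::vector<int> colcnt;
};

// Local alignment of s against the cyclic pattern pat.  Row-wise the deletion
// move wraps from the last pattern column back to the first; two sweeps per
// row reach the fixpoint because a full-cycle deletion chain (p deletions,
// zero net phase shift) is never part of an optimal alignment.
static AlnResult wdp_align(const std::vector<int8_t>& s,
                           const std::vector<uint8_t>& mask,
                           const std::string& pat, const Wt& w, Ws& ws) {
  const int n = (int)s.size(), p = (int)pat.size();
  AlnResult r;
  if (n == 0 || p == 0) return r;
  std::vector<int8_t> pc(p);
  for (int j = 0; j < p; ++j) pc[j] = (int8_t)code_of(pat[j]);

  ws.H.assign((size_t)(n + 1) * p, 0);
  ws.D.assign((size_t)(n + 1) * p, 0);
  int* H = ws.H.data();
  int8_t* D = ws.D.data();
  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    int* Hr = H + (size_t)i * p;
    const int* Hp = H + (size_t)(i - 1) * p;
    int8_t* Dr = D + (size_t)i * p;
    if (!mask.empty() && mask[i - 1]) continue;  // row stays 0: hard barrier
    const int8_t sc = s[i - 1];
    for (int j = 0; j < p; ++j) {
      const int jm = j ? j - 1 : p - 1;
      const int sub = (sc < 4 && pc[j] < 4 && sc == pc[j]) ? w.match : -w.mismatch;
      int v = Hp[jm] + sub;
      int8_t d = 1;
      const int up = Hp[j] - w.indel;
      if (up > v) { v = up; d = 2; }
      if (j > 0) {
        const int lf = Hr[j - 1] - w.indel;
        if (lf > v) { v = lf; d = 3; }
      }
      if (v <= 0) { v = 0; d = 0; }
      Hr[j] = v;
      Dr[j] = d;
    }
    for (int j = 0; j < p; ++j) {  // propagate deletions across the wrap
      const int jm = j ? j - 1 : p - 1;
      const int lf = Hr[jm] - w.indel;
      if (lf > Hr[j]) { Hr[j] = lf; Dr[j] = 3; }
    }
    for (int j = 0; j < p; ++j)
      if (Hr[j] > best) { best = Hr[j]; bi = i; bj = j; }
  }

  if (best <= 0) return r;
  r.ok = true;
  r.score = best;
  r.end = bi;
  ws.colcnt.assign((size_t)p * 4, 0);
  int i = bi, j = bj;
  for (;;) {
    const int8_t d = D[(size_t)i * p + j];
    if (d == 0) break;
    const int jm = j ? j - 1 : p - 1;
    if (d == 1) {
      const int8_t sc = s[i - 1];
      if (sc < 4 && pc[j] < 4 && sc == pc[j]) r.n_match++; else r.n_mismatch++;
      if (sc < 4) ws.colcnt[(size_t)j * 4 + sc]++;
      r.first_col = j;
      --i; j = jm;
    } else if (d == 2) {
      r.n_indel++; --i;
    } else {
      r.n_indel++; j = jm;
    }
  }
  r.start = i;

  std::string cons(p, 'A');
  for (int jj = 0; jj < p; ++jj) {
    int bc = 0, bb = -1;
    for (int b = 0; b < 4; ++b) {
      const int c = ws.colcnt[(size_t)jj * 4 + b];
      if (c > bc) { bc = c; bb = b; }  // ties keep the earlier base: A<C<G<T
    }
    cons[jj] = (bb >= 0) ? BASES[bb] : pat[jj];
  }
  r.consensus = cons;
  return r;
}

// Iterated majority-consensus refinement: realign against the column-majority
// pattern until fixpoint (or the iteration cap); keep the best-scoring round.
static AlnResult refine_pattern(const std::vector<int8_t>& s,
                                const std::vector<uint8_t>& mask,
                                std::string pat, const Wt& w, Ws& ws,
                                int max_iter = 6) {
  AlnResult best;
  std::string bestpat;
  std::string seen[6];
  for (int it = 0; it < max_iter; ++it) {
    bool cycled = false;
    for (int k = 0; k < it; ++k) if (seen[k] == pat) { cycled = true; break; }
    if (cycled) break;
    seen[it] = pat;
    AlnResult r = wdp_align(s, mask, pat, w, ws);
    if (!r.ok) break;
    if (r.score > best.score) { best = r; bestpat = pat; }
    if (r.consensus == pat) break;
    pat = r.consensus;
  }
  if (best.ok) best.consensus = bestpat;  // the pattern the score was computed against
  return best;
}

static std::string min_rotation(const std::string& x) {
  const int p = (int)x.size();
  int best = 0;
  for (int r = 1; r < p; ++r) {
    for (int t = 0; t < p; ++t) {
      const char a = x[(r + t) % p], b = x[(best + t) % p];
      if (a != b) { if (a < b) best = r; break; }
    }
  }
  if (best == 0) return x;
  return x.substr(best) + x.substr(0, best);
}

// true when x is an exact repetition of a strictly shorter unit; the tiled
// pattern (hence every alignment against it) is identical to the unit's
static bool is_power(const std::string& x) {
  const int p = (int)x.size();
  for (int d = 1; d <= p / 2; ++d) {
    if (p % d != 0) continue;
    bool ok = true;
    for (int t = d; t < p && ok; ++t) ok = (x[t] == x[t - d]);
    if (ok) return true;
  }
  return false;
}

static std::string rotate_left(const std::string& x, int k) {
  const int p = (int)x.size();
  k %= p; if (k < 0) k += p;
  return x.substr(k) + x.substr(0, k);
}

// Candidate patterns.  Small periods (<= 10): either every distinct substring
// (exhaustive mode) or substrings with an exact tandem recurrence.  Larger
// periods: positions sharing a 5-mer at distance d in (10, max_period] seed a
// candidate of period d.  All candidates deduplicated by minimal rotation.
static std::vector<std::string> collect_candidates(const std::string& seq,
                                                   int max_period,
                                                   bool exhaustive,
                                                   size_t cap = 8000) {
  const int n = (int)seq.size();
  std::unordered_set<std::string> set;
  std::vector<std::string> out;
  const int psmall = std::min(10, max_period);
  for (int p = 1; p <= psmall; ++p) {
    if (p > n) break;
    if (exhaustive) {
      for (int i = 0; i + p <= n; ++i) {
        std::string pat = min_rotation(seq.substr(i, p));
        if (!is_power(pat) && set.insert(pat).second) out.push_back(pat);
      }
    } else {
      for (int i = 0; i + 2 * p <= n; ++i) {
        if (seq.compare(i, p, seq, i + p, p) == 0) {
          std::string pat = min_rotation(seq.substr(i, p));
          if (!is_power(pat) && set.insert(pat).second) out.push_back(pat);
        }
      }
    }
  }
  if (max_period > 10 && n >= 16) {
    std::unordered_map<uint32_t, std::vector<int>> kmers;
    const int k = 5;
    for (int i = 0; i + k <= n; ++i) {
      uint32_t h = 0;
      bool okk = true;
      for (int t = 0; t < k; ++t) {
        const int c = code_of(seq[i + t]);
        if (c > 3) { okk = false; break; }
        h = h * 4 + (uint32_t)c;
      }
      if (okk) kmers[h].push_back(i);
    }
    for (auto& kv : kmers) {
      const std::vector<int>& pos = kv.second;
      for (size_t a = 0; a < pos.size(); ++a) {
        for (size_t b = a + 1; b < pos.size(); ++b) {
          const int d = pos[b] - pos[a];
          if (d <= 10) continue;
          if (d > max_period) break;
          if (pos[a] + d <= n && set.size() < cap) {
            std::string pat = min_rotation(seq.substr(pos[a], d));
            if (!is_power(pat) && set.insert(pat).second) out.push_back(pat);
          }
        }
      }
    }
  }
  return out;
}

struct Hit {
  int start, end, period, score;
  int n_match, n_mismatch, n_indel;
  std::string consensus;
};

static void scan_impl(const std::string& seq, const Wt& w, int min_score,
                      int max_period, bool exhaustive, int max_hits_per_pattern,
                      std::vector<Hit>& hits, Ws& ws) {
  const int n = (int)seq.size();
  std::vector<int8_t> s(n);
  for (int i = 0; i < n; ++i) s[i] = (int8_t)code_of(seq[i]);
  const int thr = std::max(min_score, 1);
  std::vector<std::string> cands = collect_candidates(seq, max_period, exhaustive);
  std::vector<uint8_t> mask;
  for (const std::string& pat : cands) {
    mask.assign(n, 0);
    for (int rep = 0; rep < max_hits_per_pattern; ++rep) {
      AlnResult r = refine_pattern(s, mask, pat, w, ws);
      if (!r.ok || r.score < thr) break;
      Hit h;
      h.start = r.start; h.end = r.end;
      h.period = (int)r.consensus.size();
      h.score = r.score;
      h.n_match = r.n_match; h.n_mismatch = r.n_mismatch; h.n_indel = r.n_indel;
      h.consensus = rotate_left(r.consensus, r.first_col);
      hits.push_back(h);
      for (int i = r.start; i < r.end; ++i) mask[i] = 1;
      if (r.end <= r.start) break;
    }
  }
}

// [[Rcpp::export]]
DataFrame scan_arrays_cpp(std::string seq, int match, int mismatch, int indel,
                          int min_score, int max_period, bool exhaustive = false,
                          int max_hits_per_pattern = 8) {
  Wt w{match, mismatch, indel};
  Ws ws;
  std::vector<Hit> hits;
  scan_impl(seq, w, min_score, max_period, exhaustive, max_hits_per_pattern, hits, ws);
  // drop exact duplicates found through different seeds
  std::unordered_set<std::string> seen;
  std::vector<const Hit*> keep;
  for (const Hit& h : hits) {
    std::string key = std::to_string(h.start) + ":" + std::to_string(h.end) + ":" +
                      std::to_string(h.period) + ":" + std::to_string(h.score) + ":" +
                      h.consensus;
    if (seen.insert(key).second) keep.push_back(&h);
  }
  const int m = (int)keep.size();
  IntegerVector st(m), en(m), pe(m), sc(m), nm(m), nx(m), ni(m);
  CharacterVector cs(m);
  for (int i = 0; i < m; ++i) {
    st[i] = keep[i]->start; en[i] = keep[i]->end; pe[i] = keep[i]->period;
    sc[i] = keep[i]->score; nm[i] = keep[i]->n_match; nx[i] = keep[i]->n_mismatch;
    ni[i] = keep[i]->n_indel; cs[i] = keep[i]->consensus;
  }
  return DataFrame::create(_["start"] = st, _["end"] = en, _["period"] = pe,
                           _["score"] = sc, _["n_match"] = nm,
                           _["n_mismatch"] = nx, _["n_indel"] = ni,
                           _["consensus"] = cs,
                           _["stringsAsFactors"] = false);
}

static int best_score_internal(const std::string& seq, const Wt& w,
                               int max_period, Ws& ws) {
  const int n = (int)seq.size();
  std::vector<int8_t> s(n);
  for (int i = 0; i < n; ++i) s[i] = (int8_t)code_of(seq[i]);
  std::vector<uint8_t> mask;  // empty: no barriers
  int best = 0;
  std::vector<std::string> cands = collect_candidates(seq, max_period, true);
  for (const std::string& pat : cands) {
    AlnResult r = refine_pattern(s, mask, pat, w, ws);
    if (r.ok && r.score > best) best = r.score;
  }
  return best;
}

// [[Rcpp::export]]
int wdp_best_score_cpp(std::string seq, int match, int mismatch, int indel,
                       int max_period) {
  Wt w{match, mismatch, indel};
  Ws ws;
  return best_score_internal(seq, w, max_period, ws);
}

// [[Rcpp::export]]
List wdp_array_cpp(std::string seq, std::string pattern, int match, int mismatch,
                   int indel) {
  Wt w{match, mismatch, indel};
  Ws ws;
  const int n = (int)seq.size();
  std::vector<int8_t> s(n);
  for (int i = 0; i < n; ++i) s[i] = (int8_t)code_of(seq[i]);
  std::vector<uint8_t> mask;
  AlnResult r = wdp_align(s, mask, pattern, w, ws);
  return List::create(_["score"] = r.score, _["start"] = r.start,
                      _["end"] = r.end, _["n_match"] = r.n_match,
                      _["n_mismatch"] = r.n_mismatch, _["n_indel"] = r.n_indel,
                      _["consensus"] = r.ok ? r.consensus : std::string(""));
}

// ---- independent oracle: Smith-Waterman against explicit tilings ----------

static int sw_local(const std::vector<int8_t>& s, const std::string& t,
                    const Wt& w, std::vector<int>& prev, std::vector<int>& cur) {
  const int n = (int)s.size(), m = (int)t.size();
  prev.assign(m + 1, 0);
  cur.assign(m + 1, 0);
  std::vector<int8_t> tc(m);
  for (int j = 0; j < m; ++j) tc[j] = (int8_t)code_of(t[j]);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const int8_t sc = s[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int sub = (sc < 4 && tc[j - 1] < 4 && sc == tc[j - 1]) ? w.match : -w.mismatch;
      int v = prev[j - 1] + sub;
      const int up = prev[j] - w.indel;
      if (up > v) v = up;
      const int lf = cur[j - 1] - w.indel;
      if (lf > v) v = lf;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

static std::string tile_pattern(const std::string& pat, int len) {
  std::string t;
  t.reserve(len);
  while ((int)t.size() < len) t += pat;
  t.resize(len);
  return t;
}

// [[Rcpp::export]]
int sw_tiled_score_cpp(std::string seq, std::string pattern, int match,
                       int mismatch, int indel) {
  Wt w{match, mismatch, indel};
  const int n = (int)seq.size(), p = (int)pattern.size();
  std::vector<int8_t> s(n);
  for (int i = 0; i < n; ++i) s[i] = (int8_t)code_of(seq[i]);
  std::vector<int> a, b;
  return sw_local(s, tile_pattern(pattern, n + 2 * p), w, a, b);
}

struct OracleWs {
  std::vector<int> prev, cur;
  std::vector<int8_t> tc, s;
  std::unordered_set<uint64_t> seen;
};

// Brute force: for every distinct substring pattern (deduplicated by minimal
// rotation, exact powers of shorter units skipped since their tiling is
// identical), plain Smith-Waterman of the sequence against the explicitly
// tiled pattern.  All buffers reused; no string allocation on the hot path.
static int oracle_best_internal(const std::string& seq, const Wt& w,
                                int max_period, OracleWs& o) {
  const int n = (int)seq.size();
  o.s.resize(n);
  for (int i = 0; i < n; ++i) o.s[i] = (int8_t)code_of(seq[i]);
  const int8_t* s = o.s.data();
  o.seen.clear();
  int best = 0;
  const int pmax = std::min(max_period, n);
  for (int p = 1; p <= pmax; ++p) {
    for (int i = 0; i + p <= n; ++i) {
      // skip exact powers (rotation-invariant property)
      bool power = false;
      for (int d = 1; d <= p / 2 && !power; ++d) {
        if (p % d) continue;
        bool ok = true;
        for (int t = d; t < p && ok; ++t) ok = (s[i + t] == s[i + t - d]);
        power = ok;
      }
      if (power) continue;
      // minimal rotation index
      int rot = 0;
      for (int r = 1; r < p; ++r) {
        for (int t = 0; t < p; ++t) {
          const int8_t a = s[i + (r + t) % p], b = s[i + (rot + t) % p];
          if (a != b) { if (a < b) rot = r; break; }
        }
      }
      uint64_t key = (uint64_t)p * 10000000000ULL;
      for (int t = 0; t < p; ++t) key = key * 5u + (uint64_t)s[i + (rot + t) % p];
      if (!o.seen.insert(key).second) continue;

      const int L = n + 2 * p;
      o.tc.resize(L);
      for (int t = 0; t < p; ++t) o.tc[t] = s[i + (rot + t) % p];
      for (int t = p; t < L; ++t) o.tc[t] = o.tc[t - p];
      const int8_t* tc = o.tc.data();

      o.prev.assign(L + 1, 0);
      o.cur.assign(L + 1, 0);
      for (int a2 = 1; a2 <= n; ++a2) {
        int* prev = o.prev.data();
        int* cur = o.cur.data();
        const int8_t sc = s[a2 - 1];
        cur[0] = 0;
        for (int j = 1; j <= L; ++j) {
          const int sub = (sc < 4 && tc[j - 1] < 4 && sc == tc[j - 1])
                            ? w.match : -w.mismatch;
          int v = prev[j - 1] + sub;
          const int up = prev[j] - w.indel;
          if (up > v) v = up;
          const int lf = cur[j - 1] - w.indel;
          if (lf > v) v = lf;
          if (v < 0) v = 0;
          cur[j] = v;
          if (v > best) best = v;
        }
        std::swap(o.prev, o.cur);
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
int oracle_best_score_cpp(std::string seq, int match, int mismatch, int indel,
                          int max_period) {
  Wt w{match, mismatch, indel};
  OracleWs o;
  return oracle_best_internal(seq, w, max_period, o);
}

// ---- exhaustive detector-vs-oracle comparison over {A,C} sequences --------

static inline uint32_t bitreverse(uint32_t x, int n) {
  uint32_t r = 0;
  for (int i = 0; i < n; ++i) { r = (r << 1) | (x & 1u); x >>= 1; }
  return r;
}

static std::string bits_to_seq(uint32_t x, int n) {
  std::string s(n, 'A');
  for (int i = 0; i < n; ++i)
    if ((x >> i) & 1u) s[i] = 'C';
  return s;
}

// Enumerates every {A,C} sequence of length n_min..n_max, reduced to canonical
// representatives under complement and reversal (both score-invariant; the
// invariance itself is re-verified on every sym_check_every-th sequence), and
// compares the detector's best array score with the brute-force oracle.
// [[Rcpp::export]]
List equivalence_scan_cpp(int n_min, int n_max, int match, int mismatch,
                          int indel, int max_period, int sym_check_every = 997) {
  Wt w{match, mismatch, indel};
  Ws ws;
  OracleWs ows;
  long long checked = 0, mism = 0, symviol = 0, symchecked = 0;
  std::string first_mism;
  int first_det = -1, first_orc = -1;
  long long tick = 0;
  for (int n = n_min; n <= n_max; ++n) {
    const uint32_t lim = (n >= 31) ? 0u : (1u << n);
    const uint32_t maskn = lim - 1u;
    for (uint32_t x = 0; x < lim; ++x) {
      const uint32_t xc = (~x) & maskn;
      const uint32_t xr = bitreverse(x, n);
      const uint32_t xrc = (~xr) & maskn;
      uint32_t canon = std::min(std::min(x, xc), std::min(xr, xrc));
      if (x != canon) continue;
      if ((++tick & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
      const std::string s = bits_to_seq(x, n);
      const int det = best_score_internal(s, w, max_period, ws);
      const int orc = oracle_best_internal(s, w, max_period, ows);
      ++checked;
      if (det != orc) {
        ++mism;
        if (first_mism.empty()) { first_mism = s; first_det = det; first_orc = orc; }
      }
      if (sym_check_every > 0 && (checked % sym_check_every) == 0) {
        ++symchecked;
        const uint32_t vars[3] = {xc, xr, xrc};
        for (int v = 0; v < 3; ++v) {
          const std::string sv = bits_to_seq(vars[v], n);
          if (best_score_internal(sv, w, max_period, ws) != det ||
              oracle_best_internal(sv, w, max_period, ows) != orc)
            ++symviol;
        }
      }
    }
  }
  return List::create(_["n_checked"] = (double)checked,
                      _["n_mismatch"] = (double)mism,
                      _["first_mismatch"] = first_mism,
                      _["first_detector"] = first_det,
                      _["first_oracle"] = first_orc,
                      _["n_symmetry_checked"] = (double)symchecked,
                      _["n_symmetry_violations"] = (double)symviol);
}

// ---- unit-cost global alignment for motif identity -------------------------

// Needleman-Wunsch with match +1, mismatch -1, gap -1; returns the number of
// matched columns and the total alignment length of one optimal alignment
// (traceback preference: diagonal, then gap in b, then gap in a).
// [[Rcpp::export]]
IntegerVector nw_align_cpp(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> H((size_t)(n + 1) * (m + 1));
  for (int i = 0; i <= n; ++i) H[(size_t)i * (m + 1)] = -i;
  for (int j = 0; j <= m; ++j) H[j] = -j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int sub = (a[i - 1] == b[j - 1]) ? 1 : -1;
      int v = H[(size_t)(i - 1) * (m + 1) + (j - 1)] + sub;
      v = std::max(v, H[(size_t)(i - 1) * (m + 1) + j] - 1);
      v = std::max(v, H[(size_t)i * (m + 1) + (j - 1)] - 1);
      H[(size_t)i * (m + 1) + j] = v;
    }
  }
  int i = n, j = m, matches = 0, alen = 0;
  while (i > 0 || j > 0) {
    const int cur = H[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 &&
        cur == H[(size_t)(i - 1) * (m + 1) + (j - 1)] + ((a[i - 1] == b[j - 1]) ? 1 : -1)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && cur == H[(size_t)(i - 1) * (m + 1) + j] - 1) {
      --i;
    } else {
      --j;
    }
    ++alen;
  }
  return IntegerVector::create(_["matches"] = matches, _["alen"] = alen,
                               _["score"] = H[(size_t)n * (m + 1) + m]);
}
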