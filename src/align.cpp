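#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <functional>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// 2-bit base encoding; 4 == N/other, never matches anything (including itself)
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) enc(s[i]);
  return v;
}

// [[Rcpp::export]]
std::string cpp_random_seq(int n, double gc) {
  if (n < 0) stop("negative length");
  std::string out(n, 'A');
  const char at[2] = {'A', 'T'};
  const char gcb[2] = {'G', 'C'};
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < gc) out[i] = gcb[unif_rand() < 0.5 ? 0 : 1];
    else out[i] = at[unif_rand() < 0.5 ? 0 : 1];
  }
  return out;
}

// Substitute each site with probability p_change, uniformly among the other
// three bases.  p_change = 3/4 (1 - exp(-4K/3)) is the JC69 chain marginal,
// so two independent applications of K compose to a JC branch of 2K.
// [[Rcpp::export]]
std::string cpp_mutate(std::string seq, double p_change) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = enc(seq[i]);
    if (b > 3) stop("non-ACGT character at position %d", (int)(i + 1));
    if (p_change > 0 && unif_rand() < p_change) {
      int k = (int)(unif_rand() * 3.0);
      if (k > 2) k = 2;               // guard against unif_rand() == 1
      seq[i] = bases[(b + 1 + k) % 4];
    }
  }
  return seq;
}

// ---------------------------------------------------------------------------
// banded affine-gap dynamic programming
//
// trace byte: bits 0-1 H-source (0 stop, 1 diag, 2 F/up, 3 E/left),
//             bit 2 E extended, bit 3 F extended
// Gap of length L costs gap_open + (L - 1) * gap_ext.
// ---------------------------------------------------------------------------

struct AlnResult {
  int qs, qe, ts, te;     // 0-based half-open, local coords of the DP problem
  int matches, cols, gap_cols, score;
  bool ok;
};

static const int NEG = -1000000000;

// Local (Smith-Waterman) DP over query window q[q0, q0+m) vs target window
// t[t0, t0+n), restricted to diagonals j - i in [lo, hi] (window-local).
static AlnResult banded_local(const std::vector<uint8_t>& q, int q0, int m,
                              const std::vector<uint8_t>& t, int t0, int n,
                              int lo, int hi,
                              int match, int mismatch, int gap_open, int gap_ext) {
  AlnResult res; res.ok = false; res.matches = res.cols = res.gap_cols = 0;
  res.score = 0; res.qs = res.qe = res.ts = res.te = 0;
  if (m <= 0 || n <= 0 || lo > hi) return res;
  int w = hi - lo + 1;
  // storage: column c in [1, w] of row i maps to j = i + lo + (c - 1)
  std::vector<int> Hprev(w + 2, 0), Hcur(w + 2, 0);
  std::vector<int> Fprev(w + 2, NEG), Fcur(w + 2, NEG);
  std::vector<int> Ecur(w + 2, NEG);
  std::vector<uint8_t> trace((size_t)(m + 1) * (w + 2), 0);
  int best = 0, bi = -1, bc = -1;
  const uint8_t* tp = t.data() + t0;
  for (int i = 1; i <= m; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    int base = i + lo;                  // j = base + (c - 1)
    int cmin = std::max(1, 2 - base);   // j >= 1
    int cmax = std::min(w, n - base + 1); // j <= n
    if (cmin > cmax) {
      std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
      continue;
    }
    int qc = q[q0 + i - 1];
    uint8_t* trow = trace.data() + (size_t)i * (w + 2);
    const int* Hp = Hprev.data();
    const int* Fp = Fprev.data();
    int hleft = 0, eleft = NEG;
    for (int c = cmin; c <= cmax; ++c) {
      int j = base + c - 1;
      uint8_t tr = 0;
      int e_open = hleft - gap_open;
      int e_ext  = eleft - gap_ext;
      int e = e_open >= e_ext ? e_open : e_ext;
      if (e_ext > e_open) tr = 4;
      int f_open = Hp[c + 1] - gap_open;
      int f_ext  = Fp[c + 1] - gap_ext;
      int f = f_open >= f_ext ? f_open : f_ext;
      if (f_ext > f_open) tr |= 8;
      int sub = (qc == tp[j - 1] && qc < 4) ? match : mismatch;
      int d = Hp[c] + sub;              // row 0 is all zeros: free start
      int h = 0; uint8_t src = 0;
      if (d > h) { h = d; src = 1; }
      if (f > h) { h = f; src = 2; }
      if (e > h) { h = e; src = 3; }
      Hcur[c] = h; Ecur[c] = e; Fcur[c] = f;
      trow[c] = (uint8_t)(tr | src);
      hleft = h; eleft = e;
      if (h > best) { best = h; bi = i; bc = c; }
    }
    std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
  }
  if (best <= 0) return res;
  int i = bi, c = bc;
  int j = i + lo + (c - 1);
  res.qe = i; res.te = j; res.score = best;
  int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in target)
  while (i > 0 && j > 0 && c >= 1 && c <= w) {
    uint8_t tr = trace[(size_t)i * (w + 2) + c];
    if (state == 0) {
      uint8_t src = tr & 3;
      if (src == 0) break;
      if (src == 1) {
        res.cols++;
        if (q[q0 + i - 1] < 4 && q[q0 + i - 1] == t[t0 + j - 1]) res.matches++;
        i--; j--;                      // same band column
      } else if (src == 2) state = 2;
      else state = 1;
    } else if (state == 1) {
      res.cols++; res.gap_cols++;
      bool ext = (tr & 4) != 0;
      j--; c--;
      if (!ext) state = 0;
    } else {
      res.cols++; res.gap_cols++;
      bool ext = (tr & 8) != 0;
      i--; c++;
      if (!ext) state = 0;
    }
  }
  res.qs = i; res.ts = j;
  res.ok = true;
  return res;
}

// Global (Needleman-Wunsch) banded alignment of a vs b with |j - i| <= band.
// Returns score, matches, columns, gap columns; feasible = FALSE when the
// band cannot connect the corners.
// [[Rcpp::export]]
List cpp_banded_global(std::string a, std::string b, int band,
                       int match, int mismatch, int gap_open, int gap_ext) {
  std::vector<uint8_t> q = encode_seq(a), t = encode_seq(b);
  int m = (int)q.size(), n = (int)t.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if (std::abs(n - m) > band)
    return List::create(_["feasible"] = false);
  int lo = -band, hi = band;
  int w = hi - lo + 1;
  std::vector<int> Hprev(w + 2, NEG), Hcur(w + 2, NEG);
  std::vector<int> Eprev(w + 2, NEG), Ecur(w + 2, NEG);
  std::vector<int> Fprev(w + 2, NEG), Fcur(w + 2, NEG);
  std::vector<uint8_t> trace((size_t)(m + 1) * (w + 2), 0);
  for (int c = 1; c <= w; ++c) {          // row 0: j = lo + (c - 1)
    int j = lo + (c - 1);
    if (j < 0 || j > n) continue;
    if (j == 0) Hprev[c] = 0;
    else {
      Hprev[c] = -(gap_open + (j - 1) * gap_ext);
      Eprev[c] = Hprev[c];
      trace[c] = (uint8_t)(3 | 4);
    }
  }
  const int NEGH = NEG / 2;
  for (int i = 1; i <= m; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    int base = i + lo;                  // j = base + (c - 1)
    int cmin = std::max(1, 1 - base);   // j >= 0
    int cmax = std::min(w, n - base + 1);
    if (cmin > cmax) {
      std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
      continue;
    }
    int qc = q[i - 1];
    uint8_t* trow = trace.data() + (size_t)i * (w + 2);
    const int* Hp = Hprev.data();
    const int* Fp = Fprev.data();
    int hleft = NEG, eleft = NEG;
    int c = cmin;
    if (base + c - 1 == 0) {            // first column: all gaps in target
      Hcur[c] = -(gap_open + (i - 1) * gap_ext);
      Fcur[c] = Hcur[c];
      trow[c] = (uint8_t)(2 | 8);
      hleft = Hcur[c];
      ++c;
    }
    for (; c <= cmax; ++c) {
      int j = base + c - 1;
      uint8_t tr = 0;
      int e_open = (hleft > NEGH) ? hleft - gap_open : NEG;
      int e_ext  = (eleft > NEGH) ? eleft - gap_ext : NEG;
      int e = e_open >= e_ext ? e_open : e_ext;
      if (e_ext > e_open) tr = 4;
      int f_open = (Hp[c + 1] > NEGH) ? Hp[c + 1] - gap_open : NEG;
      int f_ext  = (Fp[c + 1] > NEGH) ? Fp[c + 1] - gap_ext : NEG;
      int f = f_open >= f_ext ? f_open : f_ext;
      if (f_ext > f_open) tr |= 8;
      int sub = (qc == t[j - 1] && qc < 4) ? match : mismatch;
      int d = (Hp[c] > NEGH) ? Hp[c] + sub : NEG;
      int h = d; uint8_t src = 1;
      if (f > h) { h = f; src = 2; }
      if (e > h) { h = e; src = 3; }
      if (h <= NEGH) src = 0;
      Hcur[c] = h; Fcur[c] = f;
      trow[c] = (uint8_t)(tr | src);
      hleft = h; eleft = e;
    }
    std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
  }
  int cf = n - m - lo + 1;
  if (cf < 1 || cf > w) return List::create(_["feasible"] = false);
  int score = Hprev[cf];
  if (score <= NEG / 2) return List::create(_["feasible"] = false);
  int i = m, c = cf, j = n;
  int matches = 0, cols = 0, gap_cols = 0, state = 0;
  while (i > 0 || j > 0) {
    uint8_t tr = trace[(size_t)i * (w + 2) + c];
    if (state == 0) {
      uint8_t src = tr & 3;
      if (src == 1) {
        cols++;
        if (q[i - 1] < 4 && q[i - 1] == t[j - 1]) matches++;
        i--; j--;
      } else if (src == 2) state = 2;
      else if (src == 3) state = 1;
      else break;
    } else if (state == 1) {
      cols++; gap_cols++;
      bool ext = (tr & 4) != 0;
      j--; c--;
      if (!ext) state = 0;
    } else {
      cols++; gap_cols++;
      bool ext = (tr & 8) != 0;
      i--; c++;
      if (!ext) state = 0;
    }
    if (c < 1 || c > w) break;
  }
  return List::create(_["feasible"] = true, _["score"] = score,
                      _["matches"] = matches, _["columns"] = cols,
                      _["gap_columns"] = gap_cols);
}

// ---------------------------------------------------------------------------
// seed-and-extend local alignment
// ---------------------------------------------------------------------------

struct Cluster {
  int qlo, qhi, tlo, thi, dmin, dmax, nseed;
};

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, std::string target,
                          int k, double min_identity, int min_length,
                          int match, int mismatch, int gap_open, int gap_ext,
                          int diag_join, int gap_join, int window_pad, int band_pad) {
  std::vector<uint8_t> q = encode_seq(query), t = encode_seq(target);
  int qlen = (int)q.size(), tlen = (int)t.size();
  if (qlen == 0 || tlen == 0) stop("empty query or target");
  std::vector<int> qs_out, qe_out, ts_out, te_out, m_out, c_out, g_out, s_out;
  if (qlen >= k && tlen >= k) {
    // sorted (hash, pos) index of the target
    uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::vector<std::pair<uint64_t,int> > idx;
    idx.reserve(tlen);
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < tlen; ++i) {
      if (t[i] > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | t[i]) & mask;
      if (++run >= k) idx.push_back(std::make_pair(h, i - k + 1));
    }
    std::sort(idx.begin(), idx.end());
    std::vector<std::pair<int,int> > seeds; // (diag, tpos)
    h = 0; run = 0;
    for (int i = 0; i < qlen; ++i) {
      if (q[i] > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | q[i]) & mask;
      if (++run >= k) {
        int qpos = i - k + 1;
        auto it = std::lower_bound(idx.begin(), idx.end(),
                                   std::make_pair(h, (int)INT32_MIN));
        for (; it != idx.end() && it->first == h; ++it)
          seeds.push_back(std::make_pair(it->second - qpos, it->second));
      }
    }
    std::sort(seeds.begin(), seeds.end());
    std::vector<Cluster> cl;
    int last_tp = 0;
    for (size_t s = 0; s < seeds.size(); ++s) {
      int d = seeds[s].first, tp = seeds[s].second, qp = tp - d;
      bool fresh = cl.empty();
      if (!fresh) {
        Cluster& last = cl.back();
        if (d - last.dmax > diag_join || std::abs(tp - last_tp) > gap_join)
          fresh = true;
      }
      if (fresh) {
        Cluster nc; nc.qlo = qp; nc.qhi = qp + k; nc.tlo = tp; nc.thi = tp + k;
        nc.dmin = nc.dmax = d; nc.nseed = 1;
        cl.push_back(nc);
      } else {
        Cluster& last = cl.back();
        last.qlo = std::min(last.qlo, qp); last.qhi = std::max(last.qhi, qp + k);
        last.tlo = std::min(last.tlo, tp); last.thi = std::max(last.thi, tp + k);
        last.dmin = std::min(last.dmin, d); last.dmax = std::max(last.dmax, d);
        last.nseed++;
      }
      last_tp = tp;
    }
    // merge clusters fragmented across diagonal groups
    int C = (int)cl.size();
    if (C > 1 && C < 20000) {
      std::vector<int> parent(C);
      for (int i = 0; i < C; ++i) parent[i] = i;
      std::function<int(int)> find = [&](int x) {
        while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
        return x;
      };
      std::vector<int> ord(C);
      for (int i = 0; i < C; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return cl[a].tlo < cl[b].tlo; });
      for (int a = 0; a < C; ++a) {
        for (int b = a + 1; b < C; ++b) {
          const Cluster& A = cl[ord[a]];
          const Cluster& B = cl[ord[b]];
          if (B.tlo - A.thi > gap_join) break;
          int dgap = std::max(B.dmin - A.dmax, A.dmin - B.dmax);
          int qgap = std::max(B.qlo - A.qhi, A.qlo - B.qhi);
          if (dgap <= diag_join && qgap <= gap_join)
            parent[find(ord[a])] = find(ord[b]);
        }
      }
      std::unordered_map<int, Cluster> merged;
      for (int i = 0; i < C; ++i) {
        int r = find(i);
        auto it = merged.find(r);
        if (it == merged.end()) merged[r] = cl[i];
        else {
          Cluster& M = it->second;
          M.qlo = std::min(M.qlo, cl[i].qlo); M.qhi = std::max(M.qhi, cl[i].qhi);
          M.tlo = std::min(M.tlo, cl[i].tlo); M.thi = std::max(M.thi, cl[i].thi);
          M.dmin = std::min(M.dmin, cl[i].dmin); M.dmax = std::max(M.dmax, cl[i].dmax);
          M.nseed += cl[i].nseed;
        }
      }
      cl.clear();
      for (auto& kv : merged) cl.push_back(kv.second);
      std::sort(cl.begin(), cl.end(),
                [](const Cluster& A, const Cluster& B) {
                  return A.tlo < B.tlo || (A.tlo == B.tlo && A.qlo < B.qlo);
                });
    }
    for (const Cluster& c : cl) {
      int q0 = std::max(0, c.qlo - window_pad);
      int q1 = std::min(qlen, c.qhi + window_pad);
      int t0 = std::max(0, c.tlo - window_pad);
      int t1 = std::min(tlen, c.thi + window_pad);
      int lo = (c.dmin - band_pad) - (t0 - q0);
      int hi = (c.dmax + band_pad) - (t0 - q0);
      AlnResult r = banded_local(q, q0, q1 - q0, t, t0, t1 - t0, lo, hi,
                                 match, mismatch, gap_open, gap_ext);
      if (!r.ok || r.cols < min_length) continue;
      double ident = (double)r.matches / (double)r.cols;
      if (ident < min_identity) continue;
      qs_out.push_back(q0 + r.qs); qe_out.push_back(q0 + r.qe);
      ts_out.push_back(t0 + r.ts); te_out.push_back(t0 + r.te);
      m_out.push_back(r.matches); c_out.push_back(r.cols);
      g_out.push_back(r.gap_cols); s_out.push_back(r.score);
    }
  }
  // suppress duplicates: hits overlapping a higher-scoring kept hit by >=50%
  // of the shorter interval on both query and target are dropped
  int H = (int)qs_out.size();
  std::vector<int> ord(H);
  for (int i = 0; i < H; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return s_out[a] > s_out[b]; });
  std::vector<bool> keep(H, false);
  std::vector<int> kept;
  for (int oi = 0; oi < H; ++oi) {
    int i = ord[oi];
    bool ok = true;
    for (int j : kept) {
      int tov = std::min(te_out[i], te_out[j]) - std::max(ts_out[i], ts_out[j]);
      if (tov <= 0) continue;
      int qov = std::min(qe_out[i], qe_out[j]) - std::max(qs_out[i], qs_out[j]);
      if (qov <= 0) continue;
      int tmin = std::min(te_out[i] - ts_out[i], te_out[j] - ts_out[j]);
      int qmin = std::min(qe_out[i] - qs_out[i], qe_out[j] - qs_out[j]);
      if (tov * 2 >= tmin && qov * 2 >= qmin) { ok = false; break; }
    }
    if (ok) { keep[i] = true; kept.push_back(i); }
  }
  std::vector<int> qs2, qe2, ts2, te2, m2, c2, g2, s2;
  for (int i = 0; i < H; ++i) if (keep[i]) {
    qs2.push_back(qs_out[i]); qe2.push_back(qe_out[i]);
    ts2.push_back(ts_out[i]); te2.push_back(te_out[i]);
    m2.push_back(m_out[i]); c2.push_back(c_out[i]);
    g2.push_back(g_out[i]); s2.push_back(s_out[i]);
  }
  return DataFrame::create(_["qstart"] = qs2, _["qend"] = qe2,
                           _["tstart"] = ts2, _["tend"] = te2,
                           _["matches"] = m2, _["aligned_columns"] = c2,
                           _["gap_columns"] = g2, _["score"] = s2);
}

// Pairwise shared distinct k-mer counts for a set of sequences, forward vs
// forward ("pp") and reverse-complement vs forward ("rp"): a cheap strand-
// aware prescreen for all-vs-all alignment.
// [[Rcpp::export]]
List cpp_pair_shared(CharacterVector seqs, int k) {
  int n = seqs.size();
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  auto kset = [&](const std::string& s) {
    std::vector<uint64_t> v;
    std::vector<uint8_t> x = encode_seq(s);
    uint64_t h = 0; int run = 0;
    for (size_t i = 0; i < x.size(); ++i) {
      if (x[i] > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | x[i]) & mask;
      if (++run >= k) v.push_back(h);
    }
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    return v;
  };
  std::vector<std::vector<uint64_t> > F(n), R(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    F[i] = kset(s);
    std::string rc(s.rbegin(), s.rend());
    for (size_t p = 0; p < rc.size(); ++p) {
      switch (rc[p]) {
      case 'A': case 'a': rc[p] = 'T'; break;
      case 'C': case 'c': rc[p] = 'G'; break;
      case 'G': case 'g': rc[p] = 'C'; break;
      case 'T': case 't': rc[p] = 'A'; break;
      default: rc[p] = 'N';
      }
    }
    R[i] = kset(rc);
  }
  auto inter = [](const std::vector<uint64_t>& a,
                  const std::vector<uint64_t>& b) {
    size_t i = 0, j = 0; int c = 0;
    while (i < a.size() && j < b.size()) {
      if (a[i] < b[j]) ++i;
      else if (a[i] > b[j]) ++j;
      else { ++c; ++i; ++j; }
    }
    return c;
  };
  IntegerMatrix pp(n, n), rp(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      pp(i, j) = pp(j, i) = inter(F[i], F[j]);
      rp(i, j) = rp(j, i) = inter(R[i], F[j]);
    }
  return List::create(_["pp"] = pp, _["rp"] = rp);
}

// k-mer containment identity estimate (distinct k-mers)
// [[Rcpp::export]]
double cpp_kmer_identity(std::string a, std::string b, int k) {
  std::vector<uint8_t> x = encode_seq(a), y = encode_seq(b);
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_set<uint64_t> sa, sb;
  uint64_t h = 0; int run = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    if (x[i] > 3) { run = 0; h = 0; continue; }
    h = ((h << 2) | x[i]) & mask;
    if (++run >= k) sa.insert(h);
  }
  h = 0; run = 0;
  for (size_t i = 0; i < y.size(); ++i) {
    if (y[i] > 3) { run = 0; h = 0; continue; }
    h = ((h << 2) | y[i]) & mask;
    if (++run >= k) sb.insert(h);
  }
  if (sa.empty() || sb.empty()) return 0.0;
  const std::unordered_set<uint64_t>& small = sa.size() <= sb.size() ? sa : sb;
  const std::unordered_set<uint64_t>& big = sa.size() <= sb.size() ? sb : sa;
  size_t shared = 0;
  for (uint64_t v : small) if (big.count(v)) shared++;
  double containment = (double)shared / (double)small.size();
  return std::pow(containment, 1.0 / (double)k);
}

// Exact-k-mer anchored repeat-pair scan for the simplified structural LTR
// finder: maximal ungapped near-identical repeat pairs whose two copies lie
// min_d..max_d apart.  k-mers occurring more than max_occ times (satellite
// and telomere arrays) are skipped.
// [[Rcpp::export]]
DataFrame cpp_find_repeat_pairs(std::string seq, int k, int min_d, int max_d,
                                int max_occ, int xdrop) {
  std::vector<uint8_t> s = encode_seq(seq);
  int n = (int)s.size();
  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    if (s[i] > 3) { run = 0; h = 0; continue; }
    h = ((h << 2) | s[i]) & mask;
    if (++run >= k) {
      auto& v = idx[h];
      if ((int)v.size() <= max_occ) v.push_back(i - k + 1);
    }
  }
  std::vector<std::pair<int,int> > anchors; // (distance, p1)
  for (auto& kv : idx) {
    const std::vector<int>& v = kv.second;
    if ((int)v.size() < 2 || (int)v.size() > max_occ) continue;
    for (size_t a = 0; a < v.size(); ++a)
      for (size_t b = a + 1; b < v.size(); ++b) {
        int d = v[b] - v[a];
        if (d >= min_d && d <= max_d) anchors.push_back(std::make_pair(d, v[a]));
      }
  }
  std::sort(anchors.begin(), anchors.end());
  std::vector<int> a1o, b1o, a2o, b2o, mmo;
  int last_d = -1, covered = -1;
  const int mt = 1, mm = -3;
  for (auto& an : anchors) {
    int d = an.first, p1 = an.second, p2 = p1 + d;
    if (d != last_d) { covered = -1; last_d = d; }
    if (p1 < covered) continue;
    int score = 0, best = 0;
    int i = p1 + k, j = p2 + k, bi = i, mism = 0, mcur = 0;
    while (j < n) {
      bool eq = (s[i] == s[j] && s[i] < 4);
      score += eq ? mt : mm;
      if (!eq) mcur++;
      ++i; ++j;
      if (score > best) { best = score; bi = i; mism = mcur; }
      if (best - score > xdrop) break;
    }
    int end1 = bi, mism_total = mism;
    score = 0; best = 0;
    i = p1 - 1; j = p2 - 1; int bs = p1; mcur = 0; mism = 0;
    while (i >= 0) {
      bool eq = (s[i] == s[j] && s[i] < 4);
      score += eq ? mt : mm;
      if (!eq) mcur++;
      if (score > best) { best = score; bs = i; mism = mcur; }
      if (best - score > xdrop) break;
      --i; --j;
    }
    int start1 = bs;
    mism_total += mism;
    a1o.push_back(start1); b1o.push_back(end1);
    a2o.push_back(start1 + d); b2o.push_back(end1 + d);
    mmo.push_back(mism_total);
    covered = end1;
  }
  return DataFrame::create(_["start1"] = a1o, _["end1"] = b1o,
                           _["start2"] = a2o, _["end2"] = b2o,
                           _["mismatches"] = mmo);
}
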