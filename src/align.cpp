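#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
#include <memory>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (gap of length k costs
// open + k*ext, matching the Biostrings/BLAST convention). Sequences arrive
// as 0-based integer codes indexing the substitution matrix.
// [[Rcpp::export]]
List cpp_sw_local(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  const int n = a.size(), m = b.size();
  const int NEG = -100000000;
  // flatten the substitution matrix and sequences for tight inner loops
  const int nc = sub.ncol();
  std::vector<int> S((size_t)sub.nrow() * nc);
  for (int r = 0; r < sub.nrow(); ++r)
    for (int c = 0; c < nc; ++c) S[(size_t)r * nc + c] = sub(r, c);
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  // uninitialized DP arrays; only the boundary row/column is primed below
  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::unique_ptr<int[]> H(new int[sz]), E(new int[sz]), F(new int[sz]);
  std::unique_ptr<uint8_t[]> ptrH(new uint8_t[sz]), ptrE(new uint8_t[sz]),
      ptrF(new uint8_t[sz]);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) {
    H[idx(0, j)] = 0; F[idx(0, j)] = NEG; ptrH[idx(0, j)] = 0;
  }
  for (int i = 0; i <= n; ++i) {
    H[idx(i, 0)] = 0; E[idx(i, 0)] = NEG; ptrH[idx(i, 0)] = 0;
  }
  int best = 0, bi = 0, bj = 0;
  const int goe = gap_open + gap_ext;
  for (int i = 1; i <= n; ++i) {
    const int *Srow = &S[(size_t)av[i - 1] * nc];
    int *Hrow = &H[idx(i, 0)], *Erow = &E[idx(i, 0)], *Frow = &F[idx(i, 0)];
    const int *Hup = &H[idx(i - 1, 0)], *Fup = &F[idx(i - 1, 0)];
    uint8_t *pHrow = &ptrH[idx(i, 0)], *pErow = &ptrE[idx(i, 0)],
            *pFrow = &ptrF[idx(i, 0)];
    for (int j = 1; j <= m; ++j) {
      int e = Hrow[j - 1] - goe;
      int e2 = Erow[j - 1] - gap_ext;
      uint8_t pe = 0;
      if (e2 > e) { e = e2; pe = 1; }
      pErow[j] = pe;
      Erow[j] = e;
      int f = Hup[j] - goe;
      int f2 = Fup[j] - gap_ext;
      uint8_t pf = 0;
      if (f2 > f) { f = f2; pf = 1; }
      pFrow[j] = pf;
      Frow[j] = f;
      int d = Hup[j - 1] + Srow[bv[j - 1]];
      int h = 0; uint8_t p = 0;
      if (d > h) { h = d; p = 1; }
      if (e > h) { h = e; p = 2; }
      if (f > h) { h = f; p = 3; }
      Hrow[j] = h; pHrow[j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  int i = bi, j = bj, nid = 0, ncol = 0;
  int state = 0; // 0 H, 1 E, 2 F
  while (true) {
    if (state == 0) {
      uint8_t p = ptrH[idx(i, j)];
      if (p == 0) break;
      if (p == 1) {
        ++ncol;
        if (a[i - 1] == b[j - 1]) ++nid;
        --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++ncol;
      uint8_t p = ptrE[idx(i, j)];
      --j;
      if (p == 0) state = 0;
    } else {
      ++ncol;
      uint8_t p = ptrF[idx(i, j)];
      --i;
      if (p == 0) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["n_ident"] = nid, _["n_col"] = ncol);
}

// Ungapped X-drop extension of exact seeds; used to triage seed clusters
// before the gapped stage. Returns the best extended score per seed.
// [[Rcpp::export]]
IntegerVector cpp_ungapped_extend(IntegerVector q, IntegerVector t,
                                  IntegerMatrix sub, IntegerVector qpos,
                                  IntegerVector tpos, int k, int xdrop) {
  const int nq = q.size(), nt = t.size(), ns = qpos.size();
  IntegerVector out(ns);
  for (int s = 0; s < ns; ++s) {
    int qi = qpos[s], ti = tpos[s];
    int sc = 0;
    for (int x = 0; x < k; ++x) sc += sub(q[qi + x], t[ti + x]);
    int best = sc, cur = sc;
    // right
    int x = k;
    while (qi + x < nq && ti + x < nt) {
      cur += sub(q[qi + x], t[ti + x]);
      if (cur > best) best = cur;
      if (best - cur > xdrop) break;
      ++x;
    }
    int right_best = best;
    // left
    cur = right_best; best = right_best;
    x = 1;
    while (qi - x >= 0 && ti - x >= 0) {
      cur += sub(q[qi - x], t[ti - x]);
      if (cur > best) best = cur;
      if (best - cur > xdrop) break;
      ++x;
    }
    out[s] = best;
  }
  return out;
}

// Frameshift-aware local alignment of a protein profile consensus against
// genomic DNA. A consensus residue may align to a codon of 1..5 nt; lengths
// other than 3 incur a frameshift penalty (fs1 for +/-1 nt, fs2 for +/-2 nt).
// In-frame gaps are affine. aa_at[j] is the residue code of the codon ending
// at 0-based DNA position j (or the code for X when the codon contains N).
// [[Rcpp::export]]
List cpp_fs_align(IntegerVector prot, IntegerVector aa_at, IntegerMatrix sub,
                  int gap_open, int gap_ext, int fs1, int fs2) {
  const int n = prot.size(), m = aa_at.size();
  const int NEG = -100000000;
  const int nc = sub.ncol();
  std::vector<int> S((size_t)sub.nrow() * nc);
  for (int r = 0; r < sub.nrow(); ++r)
    for (int c = 0; c < nc; ++c) S[(size_t)r * nc + c] = sub(r, c);
  std::vector<int> aav(aa_at.begin(), aa_at.end());
  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<int> X((n + 1) * (m + 1), NEG); // dna-only gap (3 nt units)
  std::vector<int> Y((n + 1) * (m + 1), NEG); // protein-only gap
  std::vector<uint8_t> pH((n + 1) * (m + 1), 0); // 0 stop,1..5 codon len,6 X,7 Y
  std::vector<uint8_t> pX((n + 1) * (m + 1), 0);
  std::vector<uint8_t> pY((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int pi = prot[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int ij = idx(i, j);
      if (j >= 3) {
        int x = H[idx(i, j - 3)] - gap_open - gap_ext;
        int x2 = X[idx(i, j - 3)] - gap_ext;
        if (x2 > x) { x = x2; pX[ij] = 1; }
        X[ij] = x;
      }
      int y = H[idx(i - 1, j)] - gap_open - gap_ext;
      int y2 = Y[idx(i - 1, j)] - gap_ext;
      if (y2 > y) { y = y2; pY[ij] = 1; }
      Y[ij] = y;
      int h = 0; uint8_t p = 0;
      const int *Srow = &S[(size_t)pi * nc];
      for (int c = 1; c <= 5; ++c) {
        if (j < c) break;
        int sc;
        if (c == 1) sc = -fs2;
        else if (c == 2) sc = -fs1;
        else {
          sc = Srow[aav[j - 1]];
          if (c == 4) sc -= fs1;
          else if (c == 5) sc -= fs2;
        }
        int v = H[idx(i - 1, j - c)] + sc;
        if (v > h) { h = v; p = (uint8_t)c; }
      }
      if (X[ij] > h) { h = X[ij]; p = 6; }
      if (Y[ij] > h) { h = Y[ij]; p = 7; }
      H[ij] = h; pH[ij] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback; rows: op (1 codon, 2 dna-gap, 3 prot-gap), prot_pos, dna_end, ntlen
  std::vector<int> op, ppos, dend, ntl;
  int i = bi, j = bj, state = 0;
  while (true) {
    if (state == 0) {
      uint8_t p = pH[idx(i, j)];
      if (p == 0) break;
      if (p >= 1 && p <= 5) {
        op.push_back(1); ppos.push_back(i); dend.push_back(j); ntl.push_back(p);
        i -= 1; j -= p;
      } else if (p == 6) state = 1;
      else state = 2;
    } else if (state == 1) {
      op.push_back(2); ppos.push_back(i); dend.push_back(j); ntl.push_back(3);
      uint8_t p = pX[idx(i, j)];
      j -= 3;
      if (p == 0) state = 0;
    } else {
      op.push_back(3); ppos.push_back(i); dend.push_back(j); ntl.push_back(0);
      uint8_t p = pY[idx(i, j)];
      i -= 1;
      if (p == 0) state = 0;
    }
  }
  const int np = op.size();
  IntegerMatrix path(np, 4);
  for (int r = 0; r < np; ++r) { // reverse so path runs 5'->3'
    int s = np - 1 - r;
    path(r, 0) = op[s]; path(r, 1) = ppos[s];
    path(r, 2) = dend[s]; path(r, 3) = ntl[s];
  }
  colnames(path) = CharacterVector::create("op", "prot_pos", "dna_end", "ntlen");
  return List::create(_["score"] = best,
                      _["prot_start"] = i + 1, _["prot_end"] = bi,
                      _["dna_start"] = j, _["dna_end"] = bj, // 0-based half-open
                      _["path"] = path);
}

// Percent identity of the best exact-k-mer chain shared by two windows
// (forward orientation); 0 when no k-mer is shared. Codes 0..3 = ACGT,
// anything >= 4 (N) poisons the k-mers it touches.
// [[Rcpp::export]]
double cpp_window_identity(IntegerVector a, IntegerVector b, int k) {
  const int na = a.size(), nb = b.size();
  if (na < k || nb < k) return 0.0;
  std::unordered_map<uint64_t, std::vector<int> > amap;
  uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < na; ++i) {
    if (a[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)a[i]) & mask;
    if (++run >= k) amap[key].push_back(i - k + 1);
  }
  if (amap.empty()) return 0.0;
  // collect matches grouped by diagonal (posB - posA)
  std::unordered_map<int, std::vector<int> > diag; // diag -> a-positions
  key = 0; run = 0;
  for (int j = 0; j < nb; ++j) {
    if (b[j] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b[j]) & mask;
    if (++run >= k) {
      auto it = amap.find(key);
      if (it != amap.end()) {
        int jb = j - k + 1;
        for (int ia : it->second) diag[jb - ia].push_back(ia);
      }
    }
  }
  if (diag.empty()) return 0.0;
  double bestpct = 0.0;
  for (auto &dv : diag) {
    std::vector<int> &pos = dv.second;
    std::sort(pos.begin(), pos.end());
    // union length of [p, p+k) intervals over the chain span
    long covered = 0;
    int lo = pos[0], hi = pos[0] + k;
    for (size_t t = 1; t < pos.size(); ++t) {
      if (pos[t] <= hi) hi = std::max(hi, pos[t] + k);
      else { covered += hi - lo; lo = pos[t]; hi = pos[t] + k; }
    }
    covered += hi - lo;
    // floor the span so an isolated k-mer in a large window reads as weak
    // signal rather than 100% identity
    long span = (pos.back() + k) - pos.front();
    if (span < 50) span = 50;
    double pct = 100.0 * (double)covered / (double)span;
    if (pct > bestpct) bestpct = pct;
  }
  return bestpct;
}
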