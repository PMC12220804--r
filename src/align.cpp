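#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Shared alignment core for the TIR stage. Sequences are uppercase
// A/C/G/T/N strings; N scores as a mismatch against everything
// (including N). Gap model is linear: a gap of length L costs gap*L,
// matching the einverted-style scoring the R layer exposes.

static const int NEG = INT32_MIN / 4;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline int subscore(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return a == b ? match : mismatch;
}

// ---------------------------------------------------------------------------
// Global (end-to-end) alignment of a vs b with linear gaps, banded.
// band <= 0 means full matrix. Returns score plus column statistics.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap, int band = 0) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) {
    int cols = std::max(n, m);
    return List::create(_["score"] = -gap * cols, _["columns"] = cols,
                        _["matches"] = 0, _["mismatches"] = 0,
                        _["gaps"] = cols, _["identity"] = 0.0);
  }
  int bw = band;
  if (bw <= 0 || bw > std::max(n, m)) bw = std::max(n, m);
  if (bw < std::abs(n - m) + 1) bw = std::abs(n - m) + 1;

  const int W = 2 * bw + 1;
  // score rows and full traceback in band coordinates: column j maps to
  // offset j - (i - bw) within row i.
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 255);  // 0 diag, 1 up, 2 left

  auto off = [&](int i, int j) { return j - (i - bw); };
  // row 0
  for (int j = 0; j <= std::min(m, bw); ++j) {
    prev[off(0, j)] = -gap * j;
    tb[(size_t)0 * W + off(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    int jlo = std::max(0, i - bw), jhi = std::min(m, i + bw);
    for (int j = jlo; j <= jhi; ++j) {
      int o = off(i, j);
      int best = NEG; uint8_t mv = 255;
      if (j >= 1) {  // diag from (i-1, j-1): offset o in prev row
        int d = prev[o];
        if (d > NEG) {
          d += subscore(a[i - 1], b[j - 1], match, mismatch);
          if (d > best) { best = d; mv = 0; }
        }
      }
      {  // up from (i-1, j): offset o+1 in prev row
        if (o + 1 < W && prev[o + 1] > NEG) {
          int d = prev[o + 1] - gap;
          if (d > best) { best = d; mv = 1; }
        }
      }
      if (j == 0) { best = -gap * i; mv = 1; }
      {  // left from (i, j-1): offset o-1 in current row
        if (o - 1 >= 0 && cur[o - 1] > NEG) {
          int d = cur[o - 1] - gap;
          if (d > best) { best = d; mv = 2; }
        }
      }
      cur[o] = best;
      tb[(size_t)i * W + o] = mv;
    }
    std::swap(prev, cur);
  }
  int score = prev[off(n, m)];

  // traceback for column statistics and the op string
  // (M match, X mismatch, U gap consuming a, L gap consuming b)
  int i = n, j = m, columns = 0, matches = 0, mismatches = 0, gaps = 0;
  std::string ops;
  ops.reserve(n + m);
  while (i > 0 || j > 0) {
    uint8_t mv = tb[(size_t)i * W + off(i, j)];
    if (mv == 0) {
      ++columns;
      char x = a[i - 1], y = b[j - 1];
      if (x == y && x != 'N') { ++matches; ops.push_back('M'); }
      else { ++mismatches; ops.push_back('X'); }
      --i; --j;
    } else if (mv == 1) { ++columns; ++gaps; ops.push_back('U'); --i; }
    else if (mv == 2)   { ++columns; ++gaps; ops.push_back('L'); --j; }
    else stop("banded traceback fell outside the band");
  }
  std::reverse(ops.begin(), ops.end());
  double identity = columns > 0 ? 100.0 * matches / columns : 0.0;
  return List::create(_["score"] = score, _["columns"] = columns,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gaps"] = gaps, _["identity"] = identity,
                      _["ops"] = ops);
}

// ---------------------------------------------------------------------------
// Exact inverted-repeat scan (small contigs). Smith-Waterman of S against
// revcomp(S) with start tracking; iteratively reports the best valid local
// alignment (arm5 strictly upstream of arm3, insert <= max_sep), then
// removes both arm regions from further consideration.
// Coordinates returned are 0-based half-open in S.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame ir_scan_exact_cpp(std::string s, int match, int mismatch, int gap,
                            int min_score, double max_sep, int max_hits = 100) {
  const int n = (int)s.size();
  if (n > 5000) stop("exact inverted-repeat scan is limited to contigs <= 5000 bp");
  std::vector<int> a5s, a5e, a3s, a3e;
  if (n < 2) {
    return DataFrame::create(_["arm5_start"] = a5s, _["arm5_end"] = a5e,
                             _["arm3_start"] = a3s, _["arm3_end"] = a3e);
  }
  std::string y = revcomp_str(s);
  std::vector<char> banned(n, 0);

  const size_t NN = (size_t)(n + 1) * (n + 1);
  std::vector<int> H(NN), SI(NN), SJ(NN);

  for (int iter = 0; iter < max_hits; ++iter) {
    std::fill(H.begin(), H.end(), 0);
    auto idx = [&](int i, int j) { return (size_t)i * (n + 1) + j; };
    int bestH = 0, bi = -1, bj = -1;
    for (int i = 1; i <= n; ++i) {
      bool bx = banned[i - 1];
      for (int j = 1; j <= n; ++j) {
        size_t id = idx(i, j);
        if (bx || banned[n - j]) { H[id] = 0; SI[id] = 0; continue; }
        int diag = H[idx(i - 1, j - 1)] + subscore(s[i - 1], y[j - 1], match, mismatch);
        int up   = H[idx(i - 1, j)] - gap;
        int left = H[idx(i, j - 1)] - gap;
        int best = 0; int mv = -1;
        if (diag > best) { best = diag; mv = 0; }
        if (up   > best) { best = up;   mv = 1; }
        if (left > best) { best = left; mv = 2; }
        H[id] = best;
        if (mv == 0) {
          if (H[idx(i - 1, j - 1)] == 0) { SI[id] = i; SJ[id] = j; }
          else { SI[id] = SI[idx(i - 1, j - 1)]; SJ[id] = SJ[idx(i - 1, j - 1)]; }
        } else if (mv == 1) { SI[id] = SI[idx(i - 1, j)]; SJ[id] = SJ[idx(i - 1, j)]; }
        else if (mv == 2)   { SI[id] = SI[idx(i, j - 1)]; SJ[id] = SJ[idx(i, j - 1)]; }
        else { SI[id] = 0; SJ[id] = 0; }
        if (best >= min_score && i + j <= n && SI[id] > 0) {
          // insert length = arm3_end_excl - arm5_start = (n - SJ + 1) - (SI - 1)
          int ins = n - SJ[id] - SI[id] + 2;
          if (ins <= max_sep && best > bestH) { bestH = best; bi = i; bj = j; }
        }
      }
    }
    if (bi < 0) break;
    // traceback to the recorded start to recover arm extents
    int i = bi, j = bj;
    int si = SI[idx(bi, bj)], sj = SJ[idx(bi, bj)];
    // arms in S, 0-based half-open
    int arm5_start = si - 1, arm5_end = bi;
    int arm3_start = n - bj, arm3_end = n - sj + 1;
    a5s.push_back(arm5_start); a5e.push_back(arm5_end);
    a3s.push_back(arm3_start); a3e.push_back(arm3_end);
    for (int p = arm5_start; p < arm5_end; ++p) banned[p] = 1;
    for (int p = arm3_start; p < arm3_end; ++p) banned[p] = 1;
    (void)i; (void)j; (void)sj;
  }
  return DataFrame::create(_["arm5_start"] = a5s, _["arm5_end"] = a5e,
                           _["arm3_start"] = a3s, _["arm3_end"] = a3e);
}

// ---------------------------------------------------------------------------
// Seeded inverted-repeat scan (large contigs): reverse-complement k-mer
// seeding within the separation limit, banded X-drop extension.
// ---------------------------------------------------------------------------

struct Ext { int score, u, v; };  // consumed X / Y lengths at the best cell

// dir = +1: consume X at xs, xs+1, ... and Y at ys, ys+1, ...
// dir = -1: consume X at xs, xs-1, ... and Y at ys, ys-1, ...
// Positions are 0-based indices into X and Y; extension is anchored
// (score starts at 0 and may go negative within the X-drop).
static Ext xdrop_extend(const std::string& X, const std::string& Y,
                        int xs, int ys, int dir,
                        int match, int mismatch, int gap,
                        int band, int xdrop,
                        long n, double max_sep, int i0, int j0, int k) {
  const int W = 2 * band + 1;
  std::vector<int> prev(W, NEG), cur(W, NEG);
  const int nx = (int)X.size(), ny = (int)Y.size();
  // row u = number of X bases consumed; offset o = u - v + band
  Ext best{0, 0, 0};
  // row 0: pure Y gaps
  for (int v = 0; v <= band; ++v) {
    int yq = ys + dir * (v - 1);
    if (v > 0 && (yq < 0 || yq >= ny)) break;
    prev[0 - v + band] = -gap * v;
  }
  int rowmax = 0;
  for (int u = 1; ; ++u) {
    int xp = xs + dir * (u - 1);
    if (xp < 0 || xp >= nx) break;
    std::fill(cur.begin(), cur.end(), NEG);
    int newmax = NEG;
    for (int o = W - 1; o >= 0; --o) {
      int v = u - (o - band);
      if (v < 0) continue;
      int yq = ys + dir * (v - 1);
      if (v > 0 && (yq < 0 || yq >= ny)) continue;
      int sc = NEG;
      if (v >= 1 && prev[o] > NEG)
        sc = std::max(sc, prev[o] + subscore(X[xp], Y[yq], match, mismatch));
      if (o - 1 >= 0 && prev[o - 1] > NEG)          // up: (u-1, v)
        sc = std::max(sc, prev[o - 1] - gap);
      if (v == 0)
        sc = std::max(sc, -gap * u);
      if (o + 1 < W && cur[o + 1] > NEG)            // left: (u, v-1)
        sc = std::max(sc, cur[o + 1] - gap);
      if (sc <= NEG / 2) continue;
      // geometric validity at this endpoint
      if (v >= 1) {
        if (dir > 0) {
          // forward: last X pos xp, last Y pos yq; arms must not overlap
          if ((long)xp + (long)yq > n - 2) continue;
        } else {
          // backward: insert = (n - yq) - xp must stay within max_sep
          if ((double)(n - yq) - (double)xp > max_sep) continue;
        }
      }
      cur[o] = sc;
      if (sc > newmax) newmax = sc;
      if (v >= 1 && sc > best.score) { best.score = sc; best.u = u; best.v = v; }
      // pure-X-gap endpoints (v == 0) are never recorded as best: an arm
      // end must be an aligned pair.
    }
    if (newmax <= NEG / 2 || newmax < best.score - xdrop) break;
    rowmax = newmax;
    std::swap(prev, cur);
    if (u > 100000) break;  // safety
  }
  (void)rowmax; (void)i0; (void)j0; (void)k;
  return best;
}

// [[Rcpp::export]]
DataFrame ir_scan_seeded_cpp(std::string s, int k,
                             int match, int mismatch, int gap,
                             int min_score, double max_sep,
                             int band = 16, int xdrop = 100) {
  const long n = (long)s.size();
  std::vector<int> a5s, a5e, a3s, a3e, scr;
  if (n < 2 * k) {
    return DataFrame::create(_["arm5_start"] = a5s, _["arm5_end"] = a5e,
                             _["arm3_start"] = a3s, _["arm3_end"] = a3e,
                             _["ext_score"] = scr);
  }
  std::string y = revcomp_str(s);

  // packed (key, pos) list for X k-mers without N, sorted
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<uint64_t> xk;
  xk.reserve(n);
  {
    uint64_t key = 0; int valid = 0;
    for (long p = 0; p < n; ++p) {
      char c = s[p];
      int code;
      switch (c) { case 'A': code = 0; break; case 'C': code = 1; break;
                   case 'G': code = 2; break; case 'T': code = 3; break;
                   default: code = -1; }
      if (code < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)code) & mask;
      if (++valid >= k) {
        long start = p - k + 1;
        xk.push_back((key << 32) | (uint64_t)start);
      }
    }
  }
  std::sort(xk.begin(), xk.end());

  struct Box { int x1, x2, y1, y2; };
  std::vector<Box> boxes;

  // iterate Y k-mers with a rolling key
  uint64_t key = 0; int valid = 0;
  for (long p = 0; p < n; ++p) {
    char c = y[p];
    int code;
    switch (c) { case 'A': code = 0; break; case 'C': code = 1; break;
                 case 'G': code = 2; break; case 'T': code = 3; break;
                 default: code = -1; }
    if (code < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)code) & mask;
    if (++valid < k) continue;
    long j = p - k + 1;  // Y seed start
    // admissible X window: i in [n - j - max_sep, n - 2k - j]
    long ihi = n - 2 * k - j;
    if (ihi < 0) continue;
    long ilo = (long)std::max(0.0, (double)n - (double)j - max_sep);
    if (ilo > ihi) continue;
    uint64_t lo = (key << 32) | (uint64_t)ilo;
    uint64_t hi = (key << 32) | (uint64_t)ihi;
    auto it = std::lower_bound(xk.begin(), xk.end(), lo);
    for (; it != xk.end() && *it <= hi; ++it) {
      int i = (int)(*it & 0xFFFFFFFFULL);
      // skip seeds covered by an already-extended hit
      bool covered = false;
      for (const Box& b : boxes) {
        if (i >= b.x1 - k && i + k - 1 <= b.x2 + k &&
            j >= b.y1 - k && j + k - 1 <= b.y2 + k) { covered = true; break; }
      }
      if (covered) continue;
      Ext f = xdrop_extend(s, y, i + k, (int)j + k, +1, match, mismatch, gap,
                           band, xdrop, n, max_sep, i, (int)j, k);
      Ext bwd = xdrop_extend(s, y, i - 1, (int)j - 1, -1, match, mismatch, gap,
                             band, xdrop, n, max_sep, i, (int)j, k);
      int total = k * match + f.score + bwd.score;
      int x1 = i - bwd.u, x2 = i + k - 1 + f.u;      // inclusive X range
      int y1 = (int)j - bwd.v, y2 = (int)j + k - 1 + f.v;  // inclusive Y range
      if (total >= min_score) {
        // map Y range back to S: Y[q] <-> S[n-1-q]
        int arm3_start = (int)n - 1 - y2, arm3_end = (int)n - y1;
        a5s.push_back(x1); a5e.push_back(x2 + 1);
        a3s.push_back(arm3_start); a3e.push_back(arm3_end);
        scr.push_back(total);
        boxes.push_back({x1, x2, y1, y2});
      }
    }
  }
  return DataFrame::create(_["arm5_start"] = a5s, _["arm5_end"] = a5e,
                           _["arm3_start"] = a3s, _["arm3_end"] = a3e,
                           _["ext_score"] = scr);
}
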