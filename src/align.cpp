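#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// 2-bit-ish encoding; anything outside ACGT -> 4 and never matches.
static std::vector<int8_t> encode_seq(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
    case 'A': case 'a': v[i] = 0; break;
    case 'C': case 'c': v[i] = 1; break;
    case 'G': case 'g': v[i] = 2; break;
    case 'T': case 't': v[i] = 3; break;
    default: v[i] = 4;
    }
  }
  return v;
}

static const int NEG = INT32_MIN / 4;

static inline int sub_score(int8_t a, int8_t b, int match, int mismatch) {
  return (a == b && a < 4) ? match : mismatch;
}

// Banded Gotoh alignment with g aligned end-to-end ("global") and free end
// gaps on l. Band of half-width w around the diagonal j = i + offset.
// Gap of length k costs gap_open + gap_ext * k (first gap column included).
//
// Returns score = NA when no end-to-end path for g fits in the band.
// [[Rcpp::export]]
List cpp_glocal_band(std::string g_, std::string l_, int offset, int w,
                     int match, int mismatch, int gap_open, int gap_ext) {
  std::vector<int8_t> g = encode_seq(g_), l = encode_seq(l_);
  const int m = (int)g.size(), n = (int)l.size();
  const int W = 2 * w + 1;
  if ((double)(m + 1) * W > 3e8)
    stop("glocal band too large (%d x %d)", m, W);
  const int open_cost = gap_open + gap_ext;

  // score rows (band-indexed); pointer matrices over all rows
  std::vector<int> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<int> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  std::vector<int8_t> ptrM((size_t)(m + 1) * W, 0),
                      ptrX((size_t)(m + 1) * W, 0),
                      ptrY((size_t)(m + 1) * W, 0);
  // band index b corresponds to j = i + offset + (b - w)

  // row 0: free leading l
  for (int b = 0; b < W; ++b) {
    int j = 0 + offset + b - w;
    if (j >= 0 && j <= n) Mp[b] = 0;
  }

  const int LIVE = NEG / 2;
  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    size_t row = (size_t)i * W;
    // valid band indices: j = i + offset + b - w must lie in [0, n]
    int b_lo = std::max(0, w - i - offset);
    int b_hi = std::min(W - 1, n + w - i - offset);
    bool alive = false;
    const int8_t gi = g[i - 1];
    for (int b = b_lo; b <= b_hi; ++b) {
      int j = i + offset + b - w;
      if (j >= 1) {
        int best = Mp[b]; int8_t p = 0;
        if (Xp[b] > best) { best = Xp[b]; p = 1; }
        if (Yp[b] > best) { best = Yp[b]; p = 2; }
        if (best > LIVE) {
          int8_t lj = l[j - 1];
          Mc[b] = best + ((gi == lj && gi < 4) ? match : mismatch);
          ptrM[row + b] = p;
        }
      }
      if (b + 1 < W) {
        int best = Mp[b + 1] - open_cost; int8_t p = 0;
        if (Xp[b + 1] - gap_ext > best) { best = Xp[b + 1] - gap_ext; p = 1; }
        if (Yp[b + 1] - open_cost > best) {
          best = Yp[b + 1] - open_cost; p = 2;
        }
        if (best > LIVE) { Xc[b] = best; ptrX[row + b] = p; }
      }
      if (b >= 1 && j >= 1) {
        int best = Mc[b - 1] - open_cost; int8_t p = 0;
        if (Xc[b - 1] - open_cost > best) {
          best = Xc[b - 1] - open_cost; p = 1;
        }
        if (Yc[b - 1] - gap_ext > best) { best = Yc[b - 1] - gap_ext; p = 2; }
        if (best > LIVE) { Yc[b] = best; ptrY[row + b] = p; }
      }
      if (!alive && (Mc[b] > LIVE || Xc[b] > LIVE || Yc[b] > LIVE)) {
        alive = true;
      }
    }
    if (!alive) return List::create(_["score"] = NA_INTEGER);
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  // best over last row (trailing l free); ignore Y endings (a trailing gap
  // in g never helps under positive penalties but would confuse clipping)
  int best = NEG, bbest = -1; int8_t sbest = 0;
  for (int b = 0; b < W; ++b) {
    int j = m + offset + b - w;
    if (j < 0 || j > n) continue;
    if (Mp[b] > best) { best = Mp[b]; bbest = b; sbest = 0; }
    if (Xp[b] > best) { best = Xp[b]; bbest = b; sbest = 1; }
  }
  if (bbest < 0 || best <= NEG / 2)
    return List::create(_["score"] = NA_INTEGER);

  // traceback
  std::vector<int> ops;  // 0 = M(match), 1 = M(mismatch), 2 = D(g-only), 3 = I(l-only)
  int i = m, b = bbest; int8_t st = sbest;
  int j = i + offset + b - w;
  int l_end = j;
  int n_match = 0, n_mismatch = 0, n_del = 0, n_ins = 0;
  while (i > 0) {
    size_t row = (size_t)i * W;
    if (st == 0) {
      bool eq = (g[i - 1] == l[j - 1] && g[i - 1] < 4);
      ops.push_back(eq ? 0 : 1);
      if (eq) ++n_match; else ++n_mismatch;
      st = ptrM[row + b];
      --i; --j;               // band index unchanged
    } else if (st == 1) {
      ops.push_back(2); ++n_del;
      st = ptrX[row + b];
      --i; b += 1;            // (i-1, j): band index shifts +1
    } else {
      ops.push_back(3); ++n_ins;
      st = ptrY[row + b];
      --j; b -= 1;            // (i, j-1)
    }
  }
  int l_start = j + 1;
  std::reverse(ops.begin(), ops.end());

  int left_del = 0, right_del = 0;
  for (size_t k = 0; k < ops.size() && ops[k] == 2; ++k) ++left_del;
  for (size_t k = ops.size(); k > 0 && ops[k - 1] == 2; --k) ++right_del;

  return List::create(
    _["score"] = best,
    _["l_start"] = l_start, _["l_end"] = l_end,
    _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
    _["n_del"] = n_del, _["n_ins"] = n_ins,
    _["left_del"] = left_del, _["right_del"] = right_del,
    _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// Banded local (Smith-Waterman/Gotoh) alignment around diagonal
// j = i + offset with half-width w; with w >= max(m, n) this is the full
// dynamic programme. Same gap convention as cpp_glocal_band.
// [[Rcpp::export]]
List cpp_local_band(std::string a_, std::string b_, int offset, int w,
                    int match, int mismatch, int gap_open, int gap_ext) {
  std::vector<int8_t> a = encode_seq(a_), b = encode_seq(b_);
  const int m = (int)a.size(), n = (int)b.size();
  const int W = 2 * w + 1;
  if ((double)(m + 1) * W > 3e8)
    stop("local band too large (%d x %d)", m, W);
  const int open_cost = gap_open + gap_ext;

  std::vector<int> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<int> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  // pointer codes: for M, 0..2 = predecessor state, 3 = local start
  std::vector<int8_t> ptrM((size_t)(m + 1) * W, 3),
                      ptrX((size_t)(m + 1) * W, 0),
                      ptrY((size_t)(m + 1) * W, 0);

  for (int bb = 0; bb < W; ++bb) {
    int j = 0 + offset + bb - w;
    if (j >= 0 && j <= n) Mp[bb] = 0;
  }
  int best = 0, bi = -1, bb_best = -1;

  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    size_t row = (size_t)i * W;
    for (int bb = 0; bb < W; ++bb) {
      int j = i + offset + bb - w;
      if (j < 0 || j > n) continue;
      if (j >= 1) {
        int bm = Mp[bb], bx = Xp[bb], by = Yp[bb];
        int prev = bm; int8_t pp = 0;
        if (bx > prev) { prev = bx; pp = 1; }
        if (by > prev) { prev = by; pp = 2; }
        int s = sub_score(a[i - 1], b[j - 1], match, mismatch);
        int val = s; int8_t p = 3;                    // fresh local start
        if (prev > NEG / 2 && prev + s > val) { val = prev + s; p = pp; }
        if (val > 0) {
          Mc[bb] = val; ptrM[row + bb] = p;
          if (val > best) { best = val; bi = i; bb_best = bb; }
        }
      }
      if (bb + 1 < W) {
        int fromM = Mp[bb + 1] > NEG / 2 ? Mp[bb + 1] - open_cost : NEG;
        int fromY = Yp[bb + 1] > NEG / 2 ? Yp[bb + 1] - open_cost : NEG;
        int fromX = Xp[bb + 1] > NEG / 2 ? Xp[bb + 1] - gap_ext : NEG;
        int v = fromM; int8_t p = 0;
        if (fromX > v) { v = fromX; p = 1; }
        if (fromY > v) { v = fromY; p = 2; }
        if (v > NEG / 2) { Xc[bb] = v; ptrX[row + bb] = p; }
      }
      if (bb >= 1 && j >= 1) {
        int fromM = Mc[bb - 1] > NEG / 2 ? Mc[bb - 1] - open_cost : NEG;
        int fromX = Xc[bb - 1] > NEG / 2 ? Xc[bb - 1] - open_cost : NEG;
        int fromY = Yc[bb - 1] > NEG / 2 ? Yc[bb - 1] - gap_ext : NEG;
        int v = fromM; int8_t p = 0;
        if (fromX > v) { v = fromX; p = 1; }
        if (fromY > v) { v = fromY; p = 2; }
        if (v > NEG / 2) { Yc[bb] = v; ptrY[row + bb] = p; }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  if (bi < 0 || best <= 0)
    return List::create(_["score"] = 0);

  // traceback from best M cell
  std::vector<int> ops;
  int i = bi, bb = bb_best; int8_t st = 0;
  int j = i + offset + bb - w;
  int a_end = i, b_end = j;
  int n_match = 0, n_mismatch = 0, n_del = 0, n_ins = 0;
  bool done = false;
  while (!done) {
    size_t row = (size_t)i * W;
    if (st == 0) {
      bool eq = (a[i - 1] == b[j - 1] && a[i - 1] < 4);
      ops.push_back(eq ? 0 : 1);
      if (eq) ++n_match; else ++n_mismatch;
      int8_t p = ptrM[row + bb];
      --i; --j;
      if (p == 3) done = true; else st = p;
    } else if (st == 1) {
      ops.push_back(2); ++n_del;
      st = ptrX[row + bb];
      --i; bb += 1;
    } else {
      ops.push_back(3); ++n_ins;
      st = ptrY[row + bb];
      --j; bb -= 1;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(
    _["score"] = best,
    _["a_start"] = i + 1, _["a_end"] = a_end,
    _["b_start"] = j + 1, _["b_end"] = b_end,
    _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
    _["n_del"] = n_del, _["n_ins"] = n_ins,
    _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// Ungapped X-drop extension of an exact seed a[i..i+k-1] == b[j..j+k-1]
// (1-based i, j). Returns best extended segment and its score.
// [[Rcpp::export]]
List cpp_ungapped_extend(std::string a_, std::string b_, int i, int j, int k,
                         int match, int mismatch, int xdrop) {
  std::vector<int8_t> a = encode_seq(a_), b = encode_seq(b_);
  const int m = (int)a.size(), n = (int)b.size();
  int score = k * match;
  // right
  int cum = score, best = score;
  int ae = i + k - 1, be = j + k - 1;
  int p = i + k, q = j + k;
  while (p <= m && q <= n) {
    cum += sub_score(a[p - 1], b[q - 1], match, mismatch);
    if (cum > best) { best = cum; ae = p; be = q; }
    if (best - cum >= xdrop) break;
    ++p; ++q;
  }
  // left
  int as = i, bs = j;
  cum = best;
  int best2 = best;
  p = i - 1; q = j - 1;
  while (p >= 1 && q >= 1) {
    cum += sub_score(a[p - 1], b[q - 1], match, mismatch);
    if (cum > best2) { best2 = cum; as = p; bs = q; }
    if (best2 - cum >= xdrop) break;
    --p; --q;
  }
  return List::create(
    _["a_start"] = as, _["a_end"] = ae,
    _["b_start"] = bs, _["b_end"] = be,
    _["score"] = best2);
}

static inline bool kmer_code(const std::vector<int8_t>& s, int pos, int k,
                             uint64_t& code) {
  code = 0;
  for (int t = 0; t < k; ++t) {
    int8_t c = s[pos + t];
    if (c >= 4) return false;
    code = (code << 2) | (uint64_t)c;
  }
  return true;
}

// Vote on diagonal offsets (b_pos - a_pos) shared k-mers fall on; offsets
// are bucketed to width 16. Returns the winning offset (bucket centre) and
// its vote count plus the total number of k-mer hits.
// [[Rcpp::export]]
List cpp_diag_vote(std::string a_, std::string b_, int k, int max_per_kmer) {
  std::vector<int8_t> a = encode_seq(a_), b = encode_seq(b_);
  const int m = (int)a.size(), n = (int)b.size();
  if (k > 31) stop("k must be <= 31");
  if (m < k || n < k)
    return List::create(_["offset"] = 0, _["votes"] = 0, _["hits"] = 0);
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(n);
  uint64_t code;
  for (int j = 0; j + k <= n; ++j) {
    if (!kmer_code(b, j, k, code)) continue;
    auto& v = idx[code];
    if ((int)v.size() < max_per_kmer) v.push_back(j);
  }
  std::unordered_map<int, int> votes;
  long hits = 0;
  for (int i = 0; i + k <= m; ++i) {
    if (!kmer_code(a, i, k, code)) continue;
    auto it = idx.find(code);
    if (it == idx.end()) continue;
    for (int j : it->second) {
      int off = j - i;
      // vote the two nearest buckets so true offsets on a bucket edge
      // are not split
      votes[off >> 4] += 1;
      votes[(off >> 4) + 1] += 1;
      ++hits;
    }
  }
  int best_bucket = 0, best_votes = 0;
  for (auto& kv : votes) {
    if (kv.second > best_votes ||
        (kv.second == best_votes && kv.first < best_bucket)) {
      best_votes = kv.second; best_bucket = kv.first;
    }
  }
  return List::create(
    _["offset"] = best_bucket * 16,
    _["votes"] = best_votes,
    _["hits"] = (double)hits);
}
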