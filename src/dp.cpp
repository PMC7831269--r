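// Exact dynamic programs for minimal-structural-entropy coding trees.
//
// Conventions shared with the R level: bins are 1-based, intervals are
// inclusive [a..b]; entropies in bits; terms with zero cut or zero volume
// contribute 0; strict-improvement tolerance 1e-12 stabilizes tie-breaking
// so that the smallest split index / leaf count wins among equals.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double TIE_TOL = 1e-12;
static const double INF = std::numeric_limits<double>::infinity();

namespace {

struct Sums {
  int n;
  double two_m;
  const double *row_cum;   // length n+1, row_cum[i] = sum of row sums 1..i
  const double *rect;      // (n+1) x (n+1) column-major, rect[i + (n+1)*j]
                           // = sum of x[1..i, 1..j]

  double rect_at(int i, int j) const { return rect[i + (n + 1) * j]; }
  double vol(int a, int b) const { return row_cum[b] - row_cum[a - 1]; }
  double intra_both(int a, int b) const {
    return rect_at(b, b) - rect_at(a - 1, b) - rect_at(b, a - 1) +
           rect_at(a - 1, a - 1);
  }
  double cut(int a, int b) const {
    double g = vol(a, b) - intra_both(a, b);
    return g > 0 ? g : 0;
  }
  // node term: child [a..b] under parent [pa..pb]
  double H(int a, int b, int pa, int pb) const {
    if (a == pa && b == pb) return 0;
    double g = cut(a, b);
    double v = vol(a, b), vp = vol(pa, pb);
    if (g <= 0 || v <= 0 || vp <= 0) return 0;
    return -(g / two_m) * std::log2(v / vp);
  }
  // bin-level terms of a leaf [a..b]
  double leaf_bins(int a, int b) const {
    double vl = vol(a, b);
    if (vl <= 0) return 0;
    double s = 0;
    for (int i = a; i <= b; ++i) {
      double rs = row_cum[i] - row_cum[i - 1];
      if (rs > 0) s += -(rs / two_m) * std::log2(rs / vl);
    }
    return s;
  }
};

}  // namespace

// ---------------------------------------------------------------------------
// Binary DP: S(l:r, k) = minimal entropy of a binary subtree over [l..r] with
// exactly k leaves, counting the two child node terms at each split plus the
// bin terms of the leaves, but NOT the term of [l..r] itself (added by the
// caller; zero at the root).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".dp_binary_cpp")]]
List dp_binary_cpp(NumericVector row_cum, NumericMatrix rect, double two_m,
                   int kmax) {
  int n = rect.nrow() - 1;
  if (kmax < 1 || kmax > n) stop("kmax out of range");
  Sums S{n, two_m, REAL(row_cum), REAL(rect)};

  // tables indexed (l, r, k), 1-based
  size_t NL = static_cast<size_t>(n) + 1;
  size_t NK = static_cast<size_t>(kmax) + 1;
  std::vector<double> tab(NL * NL * NK, INF);
  std::vector<int> bp_i(NL * NL * NK, -1), bp_k(NL * NL * NK, -1);
  auto idx = [&](int l, int r, int k) {
    return (static_cast<size_t>(l) * NL + r) * NK + k;
  };

  for (int l = 1; l <= n; ++l)
    for (int r = l; r <= n; ++r) tab[idx(l, r, 1)] = S.leaf_bins(l, r);

  for (int len = 2; len <= n; ++len) {
    for (int l = 1; l + len - 1 <= n; ++l) {
      int r = l + len - 1;
      int kcap = std::min(kmax, len);
      for (int k = 2; k <= kcap; ++k) {
        double best = INF;
        int bi = -1, bk = -1;
        for (int i = l; i < r; ++i) {
          double hl = S.H(l, i, l, r), hr = S.H(i + 1, r, l, r);
          int k1max = std::min(k - 1, i - l + 1);
          for (int k1 = 1; k1 <= k1max; ++k1) {
            if (k - k1 > r - i) continue;
            double cand = tab[idx(l, i, k1)] + tab[idx(i + 1, r, k - k1)] +
                          hl + hr;
            if (cand < best - TIE_TOL) {
              best = cand;
              bi = i;
              bk = k1;
            }
          }
        }
        tab[idx(l, r, k)] = best;
        bp_i[idx(l, r, k)] = bi;
        bp_k[idx(l, r, k)] = bk;
      }
    }
  }

  // reconstruct a node table per k (start, end, parent; root parent = 0)
  List trees(kmax);
  NumericVector entropies(kmax);
  for (int k = 1; k <= kmax; ++k) {
    entropies[k - 1] = tab[idx(1, n, k)];
    if (!R_finite(tab[idx(1, n, k)])) {
      trees[k - 1] = R_NilValue;
      continue;
    }
    std::vector<int> st, en, pa;
    // iterative stack of (l, r, k, parent)
    struct Frame { int l, r, k, parent; };
    std::vector<Frame> stack{{1, n, k, 0}};
    while (!stack.empty()) {
      Frame f = stack.back();
      stack.pop_back();
      st.push_back(f.l);
      en.push_back(f.r);
      pa.push_back(f.parent);
      int id = static_cast<int>(st.size());
      if (f.k > 1) {
        int i = bp_i[idx(f.l, f.r, f.k)], k1 = bp_k[idx(f.l, f.r, f.k)];
        // push right first so the left child is emitted first
        stack.push_back({i + 1, f.r, f.k - k1, id});
        stack.push_back({f.l, i, k1, id});
      }
    }
    trees[k - 1] = DataFrame::create(_["start"] = wrap(st),
                                     _["end"] = wrap(en),
                                     _["parent"] = wrap(pa));
  }
  return List::create(_["entropy"] = entropies, _["trees"] = trees);
}

// ---------------------------------------------------------------------------
// Multi-nary, height-bounded DP.
//
//   full(a, b, k, h): entropy of the tree rooted at [a..b] with k leaves and
//     height <= h (root term excluded; bin terms included). k == 1 is the
//     leaf base case at any h >= 0; k >= 2 requires h >= 1.
//   part(l, r, p, k, h): entropy of >= 1 children of node [l..r] tiling
//     [l..p] with k leaves total, each child subtree of height <= h - 1,
//     including the children's node terms. The single-child decomposition is
//     allowed only while peeling (p < r), which forbids redundant
//     single-child nodes.
// ---------------------------------------------------------------------------

namespace {

struct MultiDP {
  Sums S;
  int n, kmax, hmax;
  const std::vector<char> *split_ok;  // size n+1; split after bin i allowed
  size_t NL, NK, NH;
  std::vector<double> full_tab, part_tab;
  std::vector<int> part_i, part_k;  // backpointers; i = -1 => single child

  MultiDP(const Sums &s, int kmax_, int hmax_,
          const std::vector<char> *ok)
      : S(s), n(s.n), kmax(kmax_), hmax(hmax_), split_ok(ok) {
    NL = static_cast<size_t>(n) + 1;
    NK = static_cast<size_t>(kmax) + 1;
    NH = static_cast<size_t>(hmax) + 1;
    full_tab.assign(NL * NL * NK * NH, -1.0);
    size_t np = NL * NL * NL * NK * NH;
    part_tab.assign(np, -1.0);
    part_i.assign(np, -2);
    part_k.assign(np, -2);
  }
  size_t fidx(int a, int b, int k, int h) const {
    return ((static_cast<size_t>(a) * NL + b) * NK + k) * NH + h;
  }
  size_t pidx(int l, int r, int p, int k, int h) const {
    return (((static_cast<size_t>(l) * NL + r) * NL + p) * NK + k) * NH + h;
  }
  bool can_split(int i) const {
    return split_ok == nullptr || (*split_ok)[i];
  }

  double full(int a, int b, int k, int h) {
    if (k == 1) return S.leaf_bins(a, b);
    if (h < 1 || k > b - a + 1 || k < 1) return INF;
    size_t id = fidx(a, b, k, h);
    if (full_tab[id] >= 0) return full_tab[id];
    double v = part(a, b, b, k, h);
    full_tab[id] = v;
    return v;
  }

  double part(int l, int r, int p, int k, int h) {
    if (k < 1 || k > p - l + 1) return INF;
    size_t id = pidx(l, r, p, k, h);
    if (part_tab[id] >= 0 || part_i[id] != -2) return part_tab[id];
    double best = INF;
    int bi = -2, bk = -2;
    // peel the last child [i+1..p]; left part [l..i] holds k1 leaves
    for (int i = l; i < p; ++i) {
      if (!can_split(i)) continue;
      double hterm = S.H(i + 1, p, l, r);
      for (int k1 = 1; k1 < k; ++k1) {
        if (k1 > i - l + 1 || k - k1 > p - i) continue;
        double left = part(l, r, i, k1, h);
        if (!R_finite(left)) continue;
        double cand = left + hterm + full(i + 1, p, k - k1, h - 1);
        if (cand < best - TIE_TOL) {
          best = cand;
          bi = i;
          bk = k1;
        }
      }
    }
    // close [l..p] as a single child of [l..r] (only while peeling)
    if (p < r) {
      double cand = S.H(l, p, l, r) + full(l, p, k, h - 1);
      if (cand < best - TIE_TOL) {
        best = cand;
        bi = -1;
        bk = -1;
      }
    }
    part_tab[id] = best;
    part_i[id] = bi;
    part_k[id] = bk;
    return best;
  }

  void rec_full(int a, int b, int k, int h, int parent, std::vector<int> &st,
                std::vector<int> &en, std::vector<int> &pa) {
    st.push_back(a);
    en.push_back(b);
    pa.push_back(parent);
    int id = static_cast<int>(st.size());
    if (k > 1) rec_part(a, b, b, k, h, id, st, en, pa);
  }
  void rec_part(int l, int r, int p, int k, int h, int rootid,
                std::vector<int> &st, std::vector<int> &en,
                std::vector<int> &pa) {
    size_t id = pidx(l, r, p, k, h);
    int i = part_i[id], k1 = part_k[id];
    if (i == -1) {
      rec_full(l, p, k, h - 1, rootid, st, en, pa);
    } else {
      rec_part(l, r, i, k1, h, rootid, st, en, pa);
      rec_full(i + 1, p, k - k1, h - 1, rootid, st, en, pa);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".dp_multinary_cpp")]]
List dp_multinary_cpp(NumericVector row_cum, NumericMatrix rect, double two_m,
                      int kmax, int h, IntegerVector allowed_splits) {
  int n = rect.nrow() - 1;
  if (kmax < 1 || kmax > n) stop("kmax out of range");
  if (h < 1) stop("height bound must be >= 1");
  Sums S{n, two_m, REAL(row_cum), REAL(rect)};

  std::vector<char> ok;
  const std::vector<char> *okp = nullptr;
  if (allowed_splits.size() > 0) {
    ok.assign(n + 1, 0);
    for (int v : allowed_splits) {
      if (v < 1 || v >= n) stop("allowed split index out of range");
      ok[v] = 1;
    }
    okp = &ok;
  }
  MultiDP dp(S, kmax, h, okp);

  NumericVector entropies(kmax);
  double best = INF;
  int bestk = -1;
  for (int k = 1; k <= kmax; ++k) {
    double v = dp.full(1, n, k, h);
    entropies[k - 1] = v;
    if (v < best - TIE_TOL) {
      best = v;
      bestk = k;
    }
  }
  std::vector<int> st, en, pa;
  dp.rec_full(1, n, bestk, h, 0, st, en, pa);
  return List::create(
      _["entropy"] = best, _["k"] = bestk, _["entropy_by_k"] = entropies,
      _["nodes"] = DataFrame::create(_["start"] = wrap(st),
                                     _["end"] = wrap(en),
                                     _["parent"] = wrap(pa)));
}
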