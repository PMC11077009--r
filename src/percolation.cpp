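#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Incremental (sorted-occupation) union-find percolation on an open-boundary
// rectangular lattice.  Sites are occupied in decreasing order of the field
// value, which is exactly the percentile-threshold occupation rule: after k
// additions the occupied set equals the top-k sites, i.e. occupation
// probability p = k/n.  Cluster aggregates (size, extents, first and second
// coordinate moments) are merged on the fly so that the spanning-cluster
// density P, the second-moment mean cluster size S and the gyration-based
// correlation length xi are available at any requested occupation count.

namespace {

struct UF {
  std::vector<int> parent;
  std::vector<double> s;            // cluster size
  std::vector<double> sx, sy, sx2, sy2;
  std::vector<int> minr, maxr, minc, maxc;
  std::vector<char> span;

  explicit UF(int n)
      : parent(n, -1), s(n, 0.0), sx(n, 0.0), sy(n, 0.0), sx2(n, 0.0),
        sy2(n, 0.0), minr(n, 0), maxr(n, 0), minc(n, 0), maxc(n, 0),
        span(n, 0) {}

  int find(int i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    while (parent[i] != r) { int nxt = parent[i]; parent[i] = r; i = nxt; }
    return r;
  }

  // gyration aggregate g = 2 * (s*(sx2+sy2) - sx^2 - sy^2) = 2 Rg^2 s^2
  double gyr(int r) const {
    return 2.0 * (s[r] * (sx2[r] + sy2[r]) - sx[r] * sx[r] - sy[r] * sy[r]);
  }
};

}  // namespace

// Observables of threshold percolation along the occupation sequence.
// values: field values, column-major nrow x ncol; kvals: non-decreasing
// occupied-site counts at which to record.  connectivity: 4 or 8.
// Returns a matrix length(kvals) x 4 with columns (Pi, P, S, xi).
// [[Rcpp::export]]
NumericMatrix perc_observables_cpp(NumericVector values, int nrow, int ncol,
                                   IntegerVector kvals, int connectivity) {
  const int n = nrow * ncol;
  if ((int)values.size() != n) stop("values length does not match grid");
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");

  // order sites by decreasing value, ties broken by index (stable)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return values[a] > values[b];
  });

  UF uf(n);
  std::vector<char> occ(n, 0);

  const int ndir = (connectivity == 4) ? 4 : 8;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  double tot_s2 = 0.0, tot_g = 0.0;          // all clusters
  double span_s = 0.0, span_s2 = 0.0, span_g = 0.0;  // spanning clusters

  NumericMatrix out(kvals.size(), 4);
  int next_k = 0;
  int roots_buf[9];

  int k = 0;
  // handle k = 0 entries
  while (next_k < kvals.size() && kvals[next_k] == 0) {
    out(next_k, 0) = 0; out(next_k, 1) = 0; out(next_k, 2) = 0; out(next_k, 3) = 0;
    ++next_k;
  }

  for (int step = 0; step < n && next_k < kvals.size(); ++step) {
    const int i = ord[step];
    const int r0 = i % nrow, c0 = i / nrow;

    // collect distinct neighbouring roots
    int nroots = 0;
    for (int d = 0; d < ndir; ++d) {
      const int rr = r0 + dr[d], cc = c0 + dc[d];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      const int j = rr + cc * nrow;
      if (!occ[j]) continue;
      int rt = uf.find(j);
      bool seen = false;
      for (int q = 0; q < nroots; ++q) if (roots_buf[q] == rt) { seen = true; break; }
      if (!seen) roots_buf[nroots++] = rt;
    }

    // remove involved clusters from running totals
    for (int q = 0; q < nroots; ++q) {
      const int rt = roots_buf[q];
      const double s2 = uf.s[rt] * uf.s[rt], g = uf.gyr(rt);
      tot_s2 -= s2; tot_g -= g;
      if (uf.span[rt]) { span_s -= uf.s[rt]; span_s2 -= s2; span_g -= g; }
    }

    // activate site as singleton
    occ[i] = 1;
    uf.parent[i] = i;
    uf.s[i] = 1.0;
    uf.sx[i] = r0; uf.sy[i] = c0;
    uf.sx2[i] = (double)r0 * r0; uf.sy2[i] = (double)c0 * c0;
    uf.minr[i] = uf.maxr[i] = r0;
    uf.minc[i] = uf.maxc[i] = c0;
    uf.span[i] = 0;

    // merge with neighbouring clusters (union by size)
    int root = i;
    for (int q = 0; q < nroots; ++q) {
      int a = uf.find(root), b = roots_buf[q];
      if (a == b) continue;
      if (uf.s[a] < uf.s[b]) std::swap(a, b);
      uf.parent[b] = a;
      uf.s[a] += uf.s[b];
      uf.sx[a] += uf.sx[b]; uf.sy[a] += uf.sy[b];
      uf.sx2[a] += uf.sx2[b]; uf.sy2[a] += uf.sy2[b];
      uf.minr[a] = std::min(uf.minr[a], uf.minr[b]);
      uf.maxr[a] = std::max(uf.maxr[a], uf.maxr[b]);
      uf.minc[a] = std::min(uf.minc[a], uf.minc[b]);
      uf.maxc[a] = std::max(uf.maxc[a], uf.maxc[b]);
      uf.span[a] = uf.span[a] || uf.span[b];
      root = a;
    }
    root = uf.find(root);

    // spanning test: touches both opposite edges along either axis
    const bool spans = (uf.minr[root] == 0 && uf.maxr[root] == nrow - 1) ||
                       (uf.minc[root] == 0 && uf.maxc[root] == ncol - 1);
    uf.span[root] = spans ? 1 : 0;

    const double s2 = uf.s[root] * uf.s[root], g = uf.gyr(root);
    tot_s2 += s2; tot_g += g;
    if (spans) { span_s += uf.s[root]; span_s2 += s2; span_g += g; }

    ++k;
    while (next_k < kvals.size() && kvals[next_k] == k) {
      const double fin_s = k - span_s;
      const double fin_s2 = tot_s2 - span_s2;
      const double fin_g = tot_g - span_g;
      out(next_k, 0) = span_s > 0 ? 1.0 : 0.0;
      out(next_k, 1) = span_s / n;
      out(next_k, 2) = fin_s > 0 ? fin_s2 / fin_s : 0.0;
      out(next_k, 3) = fin_s2 > 0 ? std::sqrt(fin_g / fin_s2) : 0.0;
      ++next_k;
    }
  }
  return out;
}

// Connected-component labels of an occupancy grid (open boundaries).
// Labels are 1..n_clusters in first-encounter (column-major) order; 0 marks
// unoccupied sites.
// [[Rcpp::export]]
IntegerMatrix label_clusters_cpp(LogicalMatrix occ, int connectivity) {
  const int nrow = occ.nrow(), ncol = occ.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nrow, ncol);
  std::fill(lab.begin(), lab.end(), 0);

  const int ndir = (connectivity == 4) ? 4 : 8;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  std::vector<int> stack;
  int next_label = 0;
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      if (!occ(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(r + c * nrow);
      lab(r, c) = next_label;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        const int cr = cur % nrow, cc = cur / nrow;
        for (int d = 0; d < ndir; ++d) {
          const int rr = cr + dr[d], c2 = cc + dc[d];
          if (rr < 0 || rr >= nrow || c2 < 0 || c2 >= ncol) continue;
          if (occ(rr, c2) && lab(rr, c2) == 0) {
            lab(rr, c2) = next_label;
            stack.push_back(rr + c2 * nrow);
          }
        }
      }
    }
  }
  lab.attr("n_clusters") = next_label;
  return lab;
}
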