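#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact nearest-site (Euclidean) assignment over a pixel grid. Sites may be
// at continuous coordinates (e.g. component centroids). For each pixel the
// 1-based index of the nearest site is returned; distance ties are resolved
// deterministically in favour of the site with the smaller column coordinate
// (then smaller row offset). Implemented as a per-row lower envelope of
// parabolas, O(H * (S + W)).
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_site(NumericVector site_r, NumericVector site_c,
                               int H, int W) {
  int S = site_r.size();
  IntegerMatrix out(H, W);
  if (S == 0) return out;
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (site_c[a] != site_c[b]) return site_c[a] < site_c[b];
    return a < b;
  });
  std::vector<int> v(S + 1);
  std::vector<double> z(S + 2);
  for (int r = 1; r <= H; ++r) {
    // vertical offsets for this image row
    int k = 0;
    bool empty = true;
    for (int qi = 0; qi < S; ++qi) {
      int q = ord[qi];
      double dq = (r - site_r[q]) * (r - site_r[q]);
      double cq = site_c[q];
      if (empty) {
        v[0] = q; z[0] = R_NegInf; z[1] = R_PosInf; k = 0; empty = false;
        continue;
      }
      double s = 0.0;
      bool push = true;
      while (true) {
        int p = v[k];
        double cp = site_c[p];
        double dp = (r - site_r[p]) * (r - site_r[p]);
        if (cq == cp) {
          // same column: entirely dominated by the smaller vertical offset;
          // ties keep the earlier (smaller-index) site
          if (dq >= dp) { push = false; break; }
          if (k == 0) { v[0] = q; z[1] = R_PosInf; push = false; break; }
          --k; continue;
        }
        s = ((cq * cq + dq) - (cp * cp + dp)) / (2.0 * (cq - cp));
        if (s <= z[k]) {
          if (k == 0) { v[0] = q; z[1] = R_PosInf; push = false; break; }
          --k;
        } else break;
      }
      if (push) { ++k; v[k] = q; z[k] = s; z[k + 1] = R_PosInf; }
    }
    // sweep pixels of the row; at a boundary tie the left parabola wins
    int kk = 0;
    for (int c = 1; c <= W; ++c) {
      while (z[kk + 1] < (double)c) ++kk;
      out(r - 1, c - 1) = v[kk] + 1;
    }
  }
  return out;
}
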