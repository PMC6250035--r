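#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {
struct DSU {
  std::vector<int> parent;
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
  int add() { parent.push_back((int)parent.size()); return (int)parent.size() - 1; }
};
} // namespace

// Connected-component labelling of the foreground (non-zero) pixels of a 2D
// image. connectivity is 4 or 8. Labels are positive integers ordered by the
// first (column-major) pixel of each component; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(IntegerMatrix x, int connectivity) {
  int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  DSU dsu;
  // single column-major scan; neighbours already visited:
  // (i-1, j), (i, j-1) and for 8-connectivity (i-1, j-1), (i+1, j-1)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (x(i, j) == 0) continue;
      int best = -1;
      auto consider = [&](int ii, int jj) {
        if (ii < 0 || jj < 0 || ii >= H || jj >= W) return;
        if (lab(ii, jj) > 0) {
          int l = lab(ii, jj) - 1;
          if (best < 0) best = l; else dsu.unite(best, l);
        }
      };
      consider(i - 1, j);
      consider(i, j - 1);
      if (connectivity == 8) { consider(i - 1, j - 1); consider(i + 1, j - 1); }
      if (best < 0) best = dsu.add();
      lab(i, j) = best + 1;
    }
  }
  // flatten and relabel in scan order
  std::vector<int> remap(dsu.parent.size(), 0);
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0) {
        int root = dsu.find(lab(i, j) - 1);
        if (remap[root] == 0) remap[root] = ++next;
        lab(i, j) = remap[root];
      }
  return lab;
}

// 3D connected-component labelling (connectivity 6 or 26) of a flattened
// column-major array with dim = c(H, W, D).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector x, IntegerVector dim, int connectivity) {
  int H = dim[0], W = dim[1], D = dim[2];
  R_xlen_t N = (R_xlen_t)H * W * D;
  IntegerVector lab(N);
  DSU dsu;
  auto at = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)j * H + (R_xlen_t)k * H * W;
  };
  for (int k = 0; k < D; ++k)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        R_xlen_t idx = at(i, j, k);
        if (x[idx] == 0) continue;
        int best = -1;
        auto consider = [&](int ii, int jj, int kk) {
          if (ii < 0 || jj < 0 || kk < 0 || ii >= H || jj >= W || kk >= D) return;
          R_xlen_t nb = at(ii, jj, kk);
          if (lab[nb] > 0) {
            int l = lab[nb] - 1;
            if (best < 0) best = l; else dsu.unite(best, l);
          }
        };
        if (connectivity == 6) {
          consider(i - 1, j, k); consider(i, j - 1, k); consider(i, j, k - 1);
        } else {
          // all previously-visited neighbours of the 26-neighbourhood
          for (int dk = -1; dk <= 0; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
                if (dk == 0 && dj == 0 && di == 0) continue;
                consider(i + di, j + dj, k + dk);
              }
        }
        if (best < 0) best = dsu.add();
        lab[idx] = best + 1;
      }
  std::vector<int> remap(dsu.parent.size(), 0);
  int next = 0;
  for (R_xlen_t idx = 0; idx < N; ++idx)
    if (lab[idx] > 0) {
      int root = dsu.find(lab[idx] - 1);
      if (remap[root] == 0) remap[root] = ++next;
      lab[idx] = remap[root];
    }
  return lab;
}

// Per-label pixel count and coordinate sums for a labelled 2D image.
// Returns a matrix with rows (size, sum_row, sum_col) per label.
// [[Rcpp::export]]
NumericMatrix cpp_label_stats(IntegerMatrix lab, int nlab) {
  NumericMatrix out(nlab, 3);
  int H = lab.nrow(), W = lab.ncol();
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int l = lab(i, j);
      if (l > 0) {
        out(l - 1, 0) += 1.0;
        out(l - 1, 1) += i + 1.0;
        out(l - 1, 2) += j + 1.0;
      }
    }
  return out;
}
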