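#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unit-sum discrete Gaussian taps on [-rad, rad].
static std::vector<double> gauss_taps(double sigma, double truncate, int &rad) {
  rad = (int)std::ceil(truncate * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> g(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    g[i + rad] = v;
    s += v;
  }
  for (double &v : g) v /= s;
  return g;
}

// Separable 2D Gaussian convolution with zero padding.
// [[Rcpp::export]]
NumericMatrix cpp_sep_gauss2d(NumericMatrix x, double sigma_r, double sigma_c,
                              double truncate) {
  int H = x.nrow(), W = x.ncol();
  int radr, radc;
  std::vector<double> gr = gauss_taps(sigma_r, truncate, radr);
  std::vector<double> gc = gauss_taps(sigma_c, truncate, radc);
  NumericMatrix tmp(H, W), out(H, W);
  // pass over rows (convolve along columns, i.e. vertical)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      int lo = std::max(0, i - radr), hi = std::min(H - 1, i + radr);
      for (int k = lo; k <= hi; ++k) acc += gr[k - i + radr] * x(k, j);
      tmp(i, j) = acc;
    }
  }
  // horizontal pass
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double acc = 0.0;
      int lo = std::max(0, j - radc), hi = std::min(W - 1, j + radc);
      for (int k = lo; k <= hi; ++k) acc += gc[k - j + radc] * tmp(i, k);
      out(i, j) = acc;
    }
  }
  return out;
}

// Separable 3D Gaussian convolution with zero padding; x is a dim=c(H,W,D)
// array flattened column-major.
// [[Rcpp::export]]
NumericVector cpp_sep_gauss3d(NumericVector x, IntegerVector dim,
                              NumericVector sigma, double truncate) {
  int H = dim[0], W = dim[1], D = dim[2];
  R_xlen_t N = (R_xlen_t)H * W * D;
  NumericVector a(clone(x)), b(N);
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] <= 0) continue; // sigma 0 along an axis: identity
    int rad;
    std::vector<double> g = gauss_taps(sigma[ax], truncate, rad);
    int n = dim[ax];
    R_xlen_t step = 1;
    for (int k = 0; k < ax; ++k) step *= dim[k];
    for (R_xlen_t idx = 0; idx < N; ++idx) {
      int pos = (int)((idx / step) % n);
      R_xlen_t base = idx - (R_xlen_t)pos * step;
      double acc = 0.0;
      int lo = std::max(0, pos - rad), hi = std::min(n - 1, pos + rad);
      for (int k = lo; k <= hi; ++k)
        acc += g[k - pos + rad] * a[base + (R_xlen_t)k * step];
      b[idx] = acc;
    }
    std::swap(a, b);
  }
  return a;
}

// Smoothed values of a sparse binary image evaluated on a strided grid.
// fr, fc: 1-based coordinates of foreground pixels. Evaluation points are
// rows off, off+stride, ... and likewise for columns (1-based).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_strided_sparse(IntegerVector fr, IntegerVector fc,
                                       int H, int W, double sigma,
                                       double truncate, int stride, int off) {
  int rad;
  std::vector<double> g = gauss_taps(sigma, truncate, rad);
  int nr = (H - off) / stride + 1;
  int nc = (W - off) / stride + 1;
  // partial horizontal pass: accumulate kernel weight onto strided columns
  NumericMatrix hm(H, nc);
  R_xlen_t nf = fr.size();
  for (R_xlen_t p = 0; p < nf; ++p) {
    int r = fr[p] - 1, c = fc[p] - 1;
    // strided columns c' = off-1 + t*stride with |c'-c| <= rad
    int tmin = (c - rad - (off - 1) + stride - 1) / stride;
    if (c - rad <= off - 1) tmin = 0;
    int tmax = (c + rad - (off - 1)) / stride;
    if (tmax > nc - 1) tmax = nc - 1;
    if (tmin < 0) tmin = 0;
    for (int t = tmin; t <= tmax; ++t) {
      int cc = off - 1 + t * stride;
      int d = cc - c;
      if (d < -rad || d > rad) continue;
      hm(r, t) += g[d + rad];
    }
  }
  // vertical pass at strided rows
  NumericMatrix out(nr, nc);
  for (int t = 0; t < nc; ++t) {
    for (int s = 0; s < nr; ++s) {
      int r = off - 1 + s * stride;
      double acc = 0.0;
      int lo = std::max(0, r - rad), hi = std::min(H - 1, r + rad);
      for (int k = lo; k <= hi; ++k) acc += g[k - r + rad] * hm(k, t);
      out(s, t) = acc;
    }
  }
  return out;
}

// Gaussian smoothing followed by window binning of a sparse binary image,
// computed by scattering each foreground pixel's kernel mass directly into
// the output bins. Exactly equals bin_image(gaussian_smooth(x)) with zero
// padding. Partial boundary windows are averaged over their actual size.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_binned_sparse(IntegerVector fr, IntegerVector fc,
                                      int H, int W, double sigma,
                                      double truncate, int bh, int bw) {
  int rad;
  std::vector<double> g = gauss_taps(sigma, truncate, rad);
  // cumulative taps: cg[i] = sum of g[0..i-1]
  std::vector<double> cg(2 * rad + 2, 0.0);
  for (int i = 0; i <= 2 * rad; ++i) cg[i + 1] = cg[i] + g[i];
  int nbr = (H + bh - 1) / bh, nbc = (W + bw - 1) / bw;
  NumericMatrix out(nbr, nbc);
  R_xlen_t nf = fr.size();
  // window weight: sum of g over image rows [a, b] (0-based) relative to r
  auto wsum = [&](int a, int b, int ctr) -> double {
    int lo = std::max(a, ctr - rad), hi = std::min(b, ctr + rad);
    if (lo > hi) return 0.0;
    return cg[hi - ctr + rad + 1] - cg[lo - ctr + rad];
  };
  for (R_xlen_t p = 0; p < nf; ++p) {
    int r = fr[p] - 1, c = fc[p] - 1;
    int br0 = std::max(0, (r - rad) / bh), br1 = std::min(nbr - 1, (r + rad) / bh);
    int bc0 = std::max(0, (c - rad) / bw), bc1 = std::min(nbc - 1, (c + rad) / bw);
    for (int br = br0; br <= br1; ++br) {
      double wr = wsum(br * bh, std::min(H - 1, br * bh + bh - 1), r);
      if (wr == 0.0) continue;
      for (int bc = bc0; bc <= bc1; ++bc) {
        double wc = wsum(bc * bw, std::min(W - 1, bc * bw + bw - 1), c);
        if (wc == 0.0) continue;
        out(br, bc) += wr * wc;
      }
    }
  }
  // divide by actual window pixel counts
  for (int br = 0; br < nbr; ++br) {
    int hrows = std::min(H, (br + 1) * bh) - br * bh;
    for (int bc = 0; bc < nbc; ++bc) {
      int wcols = std::min(W, (bc + 1) * bw) - bc * bw;
      out(br, bc) /= (double)hrows * wcols;
    }
  }
  return out;
}
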