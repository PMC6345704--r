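#include <Rcpp.h>
using namespace Rcpp;

// Dense 2-D cross-correlation, "same" output size.
// pad = 0: zero padding (border-ownership maps: no ownership off-canvas)
// pad = 1: replicate padding (images: avoids a spurious frame edge)
// Kernel offsets run over [-kr, kr] x [-kc, kc]; K must have odd dims.
// [[Rcpp::export]]
NumericMatrix conv2_same(const NumericMatrix& M, const NumericMatrix& K,
                         int pad = 0) {
  const int nr = M.nrow(), nc = M.ncol();
  const int kr = (K.nrow() - 1) / 2, kc = (K.ncol() - 1) / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int dj = -kc; dj <= kc; ++dj) {
        int jj = j + dj;
        if (pad == 1) jj = jj < 0 ? 0 : (jj >= nc ? nc - 1 : jj);
        else if (jj < 0 || jj >= nc) continue;
        for (int di = -kr; di <= kr; ++di) {
          int ii = i + di;
          if (pad == 1) ii = ii < 0 ? 0 : (ii >= nr ? nr - 1 : ii);
          else if (ii < 0 || ii >= nr) continue;
          acc += M(ii, jj) * K(di + kr, dj + kc);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Separable correlation with a symmetric 1-D kernel applied along rows then
// columns, zero padding. k has odd length; offsets [-m, m].
// [[Rcpp::export]]
NumericMatrix conv2_sep(const NumericMatrix& M, const NumericVector& k) {
  const int nr = M.nrow(), nc = M.ncol();
  const int m = (k.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -m; d <= m; ++d) {
        int ii = i + d;
        if (ii < 0 || ii >= nr) continue;
        acc += M(ii, j) * k[d + m];
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -m; d <= m; ++d) {
        int jj = j + d;
        if (jj < 0 || jj >= nc) continue;
        acc += tmp(i, jj) * k[d + m];
      }
      out(i, j) = acc;
    }
  return out;
}

// Sparse-tap cross-correlation, zero padding:
//   out(i, j) = sum_t w[t] * M(i + di[t], j + dj[t])
// Used for the oriented half-lobe grouping kernels, whose support is a
// narrow cone (most of a dense window would be zeros).
// [[Rcpp::export]]
NumericMatrix conv2_taps(const NumericMatrix& M, const IntegerVector& di,
                         const IntegerVector& dj, const NumericVector& w) {
  const int nr = M.nrow(), nc = M.ncol(), nt = w.size();
  NumericMatrix out(nr, nc);
  for (int t = 0; t < nt; ++t) {
    const int a = di[t], b = dj[t];
    const double wt = w[t];
    const int i0 = std::max(0, -a), i1 = std::min(nr, nr - a);
    const int j0 = std::max(0, -b), j1 = std::min(nc, nc - b);
    for (int j = j0; j < j1; ++j) {
      const double* src = &M(0, j + b);
      double* dst = &out(0, j);
      for (int i = i0; i < i1; ++i) dst[i] += wt * src[i + a];
    }
  }
  return out;
}
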