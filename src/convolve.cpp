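#include <Rcpp.h>
using namespace Rcpp;

// Separable symmetric-kernel convolution with edge replication.
// kernel must have odd length; this is the Gaussian blur inside the
// per-fixation saliency computation, the inner loop of the encoding
// pipeline, hence the interior fast path.
// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(const NumericMatrix& m,
                           const NumericVector& kernel) {
  const int h = m.nrow(), w = m.ncol();
  const int r = (kernel.size() - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  const double* kp = &kernel[0];
  // vertical pass (contiguous within a column)
  for (int j = 0; j < w; ++j) {
    const double* col = &m(0, j);
    double* tcol = &tmp(0, j);
    const int lo = std::min(r, h), hi = std::max(h - r, lo);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        int ii = i + k;
        if (ii < 0) ii = 0; else if (ii >= h) ii = h - 1;
        acc += kp[k + r] * col[ii];
      }
      tcol[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double* base = col + i - r;
      for (int k = 0; k <= 2 * r; ++k) acc += kp[k] * base[k];
      tcol[i] = acc;
    }
    for (int i = hi; i < h; ++i) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        int ii = i + k;
        if (ii < 0) ii = 0; else if (ii >= h) ii = h - 1;
        acc += kp[k + r] * col[ii];
      }
      tcol[i] = acc;
    }
  }
  // horizontal pass
  for (int j = 0; j < w; ++j) {
    double* ocol = &out(0, j);
    for (int k = -r; k <= r; ++k) {
      int jj = j + k;
      if (jj < 0) jj = 0; else if (jj >= w) jj = w - 1;
      const double* tcol = &tmp(0, jj);
      const double kk = kp[k + r];
      if (k == -r) for (int i = 0; i < h; ++i) ocol[i] = kk * tcol[i];
      else for (int i = 0; i < h; ++i) ocol[i] += kk * tcol[i];
    }
  }
  return out;
}

// Separable bilinear resampling: out(i, j) = m(sy[i], sx[j]) with bilinear
// interpolation; source coordinates are 1-based and assumed clipped to the
// matrix extent by the caller.
// [[Rcpp::export]]
NumericMatrix bilinear_cpp(const NumericMatrix& m, const NumericVector& sx,
                           const NumericVector& sy) {
  const int h = m.nrow(), w = m.ncol();
  const int ho = sy.size(), wo = sx.size();
  NumericMatrix out(ho, wo);
  std::vector<int> iy0(ho);
  std::vector<double> fy(ho);
  for (int i = 0; i < ho; ++i) {
    int r0 = (int)std::floor(sy[i]);
    if (r0 < 1) r0 = 1;
    if (r0 > h - 1) r0 = (h > 1) ? h - 1 : 1;
    iy0[i] = r0;
    fy[i] = (h > 1) ? sy[i] - r0 : 0.0;
  }
  for (int j = 0; j < wo; ++j) {
    int c0 = (int)std::floor(sx[j]);
    if (c0 < 1) c0 = 1;
    if (c0 > w - 1) c0 = (w > 1) ? w - 1 : 1;
    double fx = (w > 1) ? sx[j] - c0 : 0.0;
    const double* colA = &m(0, c0 - 1);
    const double* colB = (w > 1) ? &m(0, c0) : colA;
    double* ocol = &out(0, j);
    for (int i = 0; i < ho; ++i) {
      int r0 = iy0[i] - 1, r1 = (h > 1) ? iy0[i] : r0;
      double a = colA[r0] * (1 - fx) + colB[r0] * fx;
      double b = colA[r1] * (1 - fx) + colB[r1] * fx;
      ocol[i] = a * (1 - fy[i]) + b * fy[i];
    }
  }
  return out;
}

// Mean of a matrix over each patch_px x patch_px grid region, returned in
// row-major region order; pixels beyond the tiled area are ignored.
// [[Rcpp::export]]
NumericVector region_mean_cpp(const NumericMatrix& m, const int patch,
                              const int n_rows, const int n_cols) {
  NumericVector out(n_rows * n_cols);
  const int h = n_rows * patch, w = n_cols * patch;
  for (int j = 0; j < w && j < m.ncol(); ++j) {
    const int gc = j / patch;
    const double* col = &m(0, j);
    for (int i = 0; i < h && i < m.nrow(); ++i)
      out[(i / patch) * n_cols + gc] += col[i];
  }
  const double npx = (double)patch * patch;
  for (int k = 0; k < out.size(); ++k) out[k] /= npx;
  return out;
}
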