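// Memory-bound kernels for the 1-D convolution stack: im2col/col2im with
// "same" zero padding and max-pooling with argmax. Tensors are R arrays in
// [batch, length, channels] layout (batch index fastest); the matrix-matrix
// products themselves stay in R so they use the installed BLAS.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector X, int k) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], L = d[1], C = d[2];
  const int pad = (k - 1) / 2;
  NumericMatrix col(B * L, k * C);
  const double *xs = X.begin();
  double *cs = col.begin();
  const R_xlen_t colrows = (R_xlen_t)B * L;
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;                  // source l offset
    for (int c = 0; c < C; ++c) {
      double *dst = cs + ((R_xlen_t)(j * C + c)) * colrows;
      const double *src = xs + (R_xlen_t)c * B * L;
      const int l_lo = std::max(0, -off), l_hi = std::min(L, L - off);
      if (l_lo > 0) std::memset(dst, 0, sizeof(double) * (size_t)l_lo * B);
      if (l_hi < L) std::memset(dst + (R_xlen_t)l_hi * B, 0,
                                sizeof(double) * (size_t)(L - l_hi) * B);
      if (l_hi > l_lo)
        std::memcpy(dst + (R_xlen_t)l_lo * B,
                    src + (R_xlen_t)(l_lo + off) * B,
                    sizeof(double) * (size_t)(l_hi - l_lo) * B);
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, int k, int B, int L, int C) {
  const int pad = (k - 1) / 2;
  NumericVector dX((R_xlen_t)B * L * C);
  dX.attr("dim") = IntegerVector::create(B, L, C);
  double *xd = dX.begin();
  const double *cd = dcol.begin();
  const R_xlen_t colrows = (R_xlen_t)B * L;
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    for (int c = 0; c < C; ++c) {
      const double *src = cd + ((R_xlen_t)(j * C + c)) * colrows;
      double *dst = xd + (R_xlen_t)c * B * L;
      const int l_lo = std::max(0, -off), l_hi = std::min(L, L - off);
      for (int l = l_lo; l < l_hi; ++l) {
        double *drow = dst + (R_xlen_t)(l + off) * B;
        const double *srow = src + (R_xlen_t)l * B;
        for (int b = 0; b < B; ++b) drow[b] += srow[b];
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector X, int m) {
  IntegerVector d = X.attr("dim");
  const int B = d[0], L = d[1], C = d[2];
  const int Lg = L / m;
  NumericVector out((R_xlen_t)B * Lg * C);
  IntegerVector amax((R_xlen_t)B * Lg * C);
  out.attr("dim") = IntegerVector::create(B, Lg, C);
  amax.attr("dim") = IntegerVector::create(B, Lg, C);
  const double *xs = X.begin();
  double *os = out.begin();
  int *as = amax.begin();
  for (int c = 0; c < C; ++c) {
    for (int g = 0; g < Lg; ++g) {
      const double *base = xs + ((R_xlen_t)c * L + (R_xlen_t)g * m) * B;
      double *orow = os + ((R_xlen_t)c * Lg + g) * B;
      int *arow = as + ((R_xlen_t)c * Lg + g) * B;
      for (int b = 0; b < B; ++b) { orow[b] = base[b]; arow[b] = 1; }
      for (int j = 1; j < m; ++j) {
        const double *row = base + (R_xlen_t)j * B;
        for (int b = 0; b < B; ++b) {
          if (row[b] > orow[b]) { orow[b] = row[b]; arow[b] = j + 1; }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector amax,
                              int m, int L) {
  IntegerVector d = dout.attr("dim");
  const int B = d[0], Lg = d[1], C = d[2];
  NumericVector dX((R_xlen_t)B * L * C);
  dX.attr("dim") = IntegerVector::create(B, L, C);
  const double *ds = dout.begin();
  const int *as = amax.begin();
  double *xs = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int g = 0; g < Lg; ++g) {
      const double *drow = ds + ((R_xlen_t)c * Lg + g) * B;
      const int *arow = as + ((R_xlen_t)c * Lg + g) * B;
      double *base = xs + ((R_xlen_t)c * L + (R_xlen_t)g * m) * B;
      for (int b = 0; b < B; ++b) {
        base[(R_xlen_t)(arow[b] - 1) * B + b] = drow[b];
      }
    }
  }
  return dX;
}

// In-place elementwise helpers. These mutate their first argument and return
// it; callers only pass freshly allocated matrices whose other references
// are never reused.

// [[Rcpp::export]]
NumericMatrix cpp_add_bias(NumericMatrix M, NumericVector b) {
  const R_xlen_t n = M.nrow();
  for (int j = 0; j < M.ncol(); ++j) {
    double *col = M.begin() + (R_xlen_t)j * n;
    const double bj = b[j];
    for (R_xlen_t i = 0; i < n; ++i) col[i] += bj;
  }
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_fwd(NumericMatrix M) {
  double *p = M.begin();
  const R_xlen_t n = (R_xlen_t)M.nrow() * M.ncol();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return M;
}

// zero the gradient wherever the cached activation was clipped
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(NumericMatrix dM, NumericVector out) {
  double *g = dM.begin();
  const double *o = out.begin();
  const R_xlen_t n = (R_xlen_t)dM.nrow() * dM.ncol();
  for (R_xlen_t i = 0; i < n; ++i) if (o[i] <= 0) g[i] = 0;
  return dM;
}

// one-pass per-column mean and (population) variance of a flat [n x C]
// column-major buffer
// [[Rcpp::export]]
List cpp_colstats(NumericVector X, int C) {
  const R_xlen_t n = X.size() / C;
  NumericVector mu(C), va(C);
  for (int j = 0; j < C; ++j) {
    const double *xc = X.begin() + (R_xlen_t)j * n;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / n;
    mu[j] = m;
    va[j] = s2 / n - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// returns xhat = (X - mu) * inv and out = gamma * xhat + beta, one pass over
// a flat [n x C] column-major buffer
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector X, int C, NumericVector mu, NumericVector inv,
                NumericVector gamma, NumericVector beta) {
  const R_xlen_t n = X.size() / C;
  NumericVector xhat(X.size()), out(X.size());
  for (int j = 0; j < C; ++j) {
    const double *xc = X.begin() + (R_xlen_t)j * n;
    double *hc = xhat.begin() + (R_xlen_t)j * n;
    double *oc = out.begin() + (R_xlen_t)j * n;
    const double m = mu[j], iv = inv[j], g = gamma[j], b = beta[j];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * iv;
      hc[i] = h;
      oc[i] = g * h + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// per-column sums of dout and dout*xhat, one pass
// [[Rcpp::export]]
List cpp_bn_grads(NumericVector dout, NumericVector xhat, int C) {
  const R_xlen_t n = dout.size() / C;
  NumericVector dgamma(C), dbeta(C);
  for (int j = 0; j < C; ++j) {
    const double *dc = dout.begin() + (R_xlen_t)j * n;
    const double *hc = xhat.begin() + (R_xlen_t)j * n;
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < n; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    dgamma[j] = sg;
    dbeta[j] = sb;
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// dx = coef_j * (dout - c1_j - xhat * c2_j), in place on dout
// [[Rcpp::export]]
NumericVector cpp_bn_bwd(NumericVector dout, NumericVector xhat, int C,
                         NumericVector coef, NumericVector c1,
                         NumericVector c2) {
  const R_xlen_t n = dout.size() / C;
  for (int j = 0; j < C; ++j) {
    double *dc = dout.begin() + (R_xlen_t)j * n;
    const double *hc = xhat.begin() + (R_xlen_t)j * n;
    const double k = coef[j], a = c1[j], b = c2[j];
    for (R_xlen_t i = 0; i < n; ++i) dc[i] = k * (dc[i] - a - hc[i] * b);
  }
  return dout;
}

// inverted dropout using R's RNG stream (respects set.seed); scales the
// input in place and returns the byte mask for the backward pass
// [[Rcpp::export]]
List cpp_dropout_fwd(NumericVector X, double rate) {
  const R_xlen_t n = X.size();
  RawVector mask(n);
  const double keep = 1.0 - rate;
  const double scale = 1.0 / keep;
  double *x = X.begin();
  Rbyte *m = mask.begin();
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (unif_rand() < keep) { m[i] = 1; x[i] *= scale; }
    else { m[i] = 0; x[i] = 0; }
  }
  PutRNGstate();
  return List::create(_["out"] = X, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector cpp_dropout_bwd(NumericVector dX, RawVector mask, double rate) {
  const double scale = 1.0 / (1.0 - rate);
  double *g = dX.begin();
  const Rbyte *m = mask.begin();
  const R_xlen_t n = dX.size();
  for (R_xlen_t i = 0; i < n; ++i) g[i] = m[i] ? g[i] * scale : 0.0;
  return dX;
}
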