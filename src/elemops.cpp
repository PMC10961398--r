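// Elementwise / per-channel helpers for batch normalization and ReLU on
// (H, W, C, N) batches. The channel axis is the third one, so per-channel
// reductions and affine maps walk contiguous H*W panels.

#include <Rcpp.h>
using namespace Rcpp;

static R_xlen_t panel_of(const NumericVector& x, int ch) {
  IntegerVector d = x.attr("dim");
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  if (d[2] != ch) stop("channel extent mismatch");
  return hw;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(const NumericVector& x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xs = x.begin();
  double* ys = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) ys[i] = xs[i] > 0 ? xs[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(const NumericVector& y, const NumericVector& gy) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* ys = y.begin();
  const double* gs = gy.begin();
  double* d = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) d[i] = ys[i] > 0 ? gs[i] : 0;
  return gx;
}

// y[.,.,c,n] = scale[c] * x[.,.,c,n] + shift[c]
// [[Rcpp::export]]
NumericVector channel_affine_cpp(const NumericVector& x,
                                 const NumericVector& scale,
                                 const NumericVector& shift) {
  R_xlen_t hw = panel_of(x, scale.size());
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const int C = scale.size();
  const R_xlen_t panels = x.size() / hw;
  const double* xs = x.begin();
  double* ys = y.begin();
  for (R_xlen_t p = 0; p < panels; ++p) {
    const double a = scale[p % C], b = shift[p % C];
    const double* xp = xs + p * hw;
    double* yp = ys + p * hw;
    for (R_xlen_t i = 0; i < hw; ++i) yp[i] = a * xp[i] + b;
  }
  return y;
}

// per-channel sum over H, W and N
// [[Rcpp::export]]
NumericVector chan_sum_cpp(const NumericVector& x, int ch) {
  R_xlen_t hw = panel_of(x, ch);
  NumericVector out(ch);
  const R_xlen_t panels = x.size() / hw;
  const double* xs = x.begin();
  for (R_xlen_t p = 0; p < panels; ++p) {
    const double* xp = xs + p * hw;
    double acc = 0;
    for (R_xlen_t i = 0; i < hw; ++i) acc += xp[i];
    out[p % ch] += acc;
  }
  return out;
}

// per-channel sum of elementwise products
// [[Rcpp::export]]
NumericVector chan_dot_cpp(const NumericVector& x, const NumericVector& y,
                           int ch) {
  R_xlen_t hw = panel_of(x, ch);
  NumericVector out(ch);
  const R_xlen_t panels = x.size() / hw;
  const double* xs = x.begin();
  const double* ys = y.begin();
  for (R_xlen_t p = 0; p < panels; ++p) {
    const double* xp = xs + p * hw;
    const double* yp = ys + p * hw;
    double acc = 0;
    for (R_xlen_t i = 0; i < hw; ++i) acc += xp[i] * yp[i];
    out[p % ch] += acc;
  }
  return out;
}

// gx = inv[c] * (dxhat - m1[c] - xhat * m2[c])
// [[Rcpp::export]]
NumericVector bn_input_grad_cpp(const NumericVector& xhat,
                                const NumericVector& dxhat,
                                const NumericVector& inv,
                                const NumericVector& m1,
                                const NumericVector& m2) {
  R_xlen_t hw = panel_of(xhat, inv.size());
  NumericVector gx(xhat.size());
  gx.attr("dim") = xhat.attr("dim");
  const int C = inv.size();
  const R_xlen_t panels = xhat.size() / hw;
  const double* hs = xhat.begin();
  const double* ds = dxhat.begin();
  double* gs = gx.begin();
  for (R_xlen_t p = 0; p < panels; ++p) {
    const double iv = inv[p % C], a = m1[p % C], b = m2[p % C];
    const double* hp = hs + p * hw;
    const double* dp = ds + p * hw;
    double* gp = gs + p * hw;
    for (R_xlen_t i = 0; i < hw; ++i)
      gp[i] = iv * (dp[i] - a - hp[i] * b);
  }
  return gx;
}
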