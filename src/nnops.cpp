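// Low-level batched tensor kernels for the segmentation network.
//
// Layout conventions (match the R wrappers in R/nn-primitives.R):
//   * a batch is a dense array of dims (H, W, C, N), column-major;
//   * a convolution weight is a matrix of dims (k*k*Cin) x Cout whose row
//     index is r = ci*k*k + kj*k + ki with ki the kernel row offset and kj
//     the kernel column offset;
//   * im2col uses a (H*Wb) x (k*k*Cin) layout (spatial rows, tap columns),
//     so the inner copy loops run down contiguous image columns and the
//     branch product is one (HW x kkC) * (kkC x Cout) GEMM per block.
//
// Convolutions are stride-1, zero-padded to preserve the spatial size
// (pad = dilation*(k-1)/2, odd k), the only form the network uses;
// downsampling is 2x2 max pooling, upsampling bilinear x2. im2col buffers
// are built in column blocks to bound peak memory on 512x512 inputs.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const arma::uword COL_BLOCK_DOUBLES = 6000000; // ~48 MB per buffer

static IntegerVector dims_of(const NumericVector& x) {
  if (!x.hasAttribute("dim")) stop("input must be a dim-ed array");
  return x.attr("dim");
}

// fill the (H*wb) x (kk*C) block for image columns [w0, w0+wb)
static void im2col_block(const double* x, arma::uword H, arma::uword W,
                         arma::uword C, arma::mat& col,
                         int k, int dil, int pad,
                         arma::uword w0, arma::uword wb) {
  const arma::uword kk = (arma::uword)k * k;
  for (arma::uword ci = 0; ci < C; ++ci) {
    const double* xc = x + ci * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* dst = col.colptr(ci * kk + kj * k + ki);
        const long oi = (long)ki * dil - pad; // row offset into source
        for (arma::uword wi = 0; wi < wb; ++wi) {
          const long sj = (long)(w0 + wi) + kj * dil - pad;
          double* d = dst + wi * H;
          if (sj < 0 || sj >= (long)W) {
            std::memset(d, 0, H * sizeof(double));
            continue;
          }
          const double* s = xc + (arma::uword)sj * H;
          // valid hi range: 0 <= hi + oi < H
          const long lo = std::max<long>(0, -oi);
          const long hi_end = std::min<long>((long)H, (long)H - oi);
          if (lo > 0) std::memset(d, 0, lo * sizeof(double));
          if (hi_end > lo)
            std::memcpy(d + lo, s + lo + oi, (hi_end - lo) * sizeof(double));
          if (hi_end < (long)H)
            std::memset(d + std::max<long>(hi_end, 0), 0,
                        (H - std::max<long>(hi_end, 0)) * sizeof(double));
        }
      }
    }
  }
}

// scatter-add the (H*wb) x (kk*C) gradient block back into gx
static void col2im_block(double* gx, arma::uword H, arma::uword W,
                         arma::uword C, const arma::mat& col,
                         int k, int dil, int pad,
                         arma::uword w0, arma::uword wb) {
  const arma::uword kk = (arma::uword)k * k;
  for (arma::uword ci = 0; ci < C; ++ci) {
    double* xc = gx + ci * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* src = col.colptr(ci * kk + kj * k + ki);
        const long oi = (long)ki * dil - pad;
        for (arma::uword wi = 0; wi < wb; ++wi) {
          const long sj = (long)(w0 + wi) + kj * dil - pad;
          if (sj < 0 || sj >= (long)W) continue;
          double* d = xc + (arma::uword)sj * H;
          const double* s = src + wi * H;
          const long lo = std::max<long>(0, -oi);
          const long hi_end = std::min<long>((long)H, (long)H - oi);
          for (long h = lo; h < hi_end; ++h) d[h + oi] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(const NumericVector& x, const arma::mat& w,
                             const arma::vec& b, int k, int dilation) {
  IntegerVector d = dims_of(x);
  const arma::uword H = d[0], W = d[1], C = d[2],
                    N = d.size() > 3 ? d[3] : 1;
  const arma::uword kk = (arma::uword)k * k;
  if (w.n_rows != kk * C)
    stop("conv2d: weight rows (%d) != k*k*Cin (%d)",
         (int)w.n_rows, (int)(kk * C));
  const arma::uword Cout = w.n_cols;
  const int pad = dilation * (k - 1) / 2;

  NumericVector y(H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::uword wb_max = std::max<arma::uword>(
    1, COL_BLOCK_DOUBLES / std::max<arma::uword>(1, kk * C * H));
  wb_max = std::min<arma::uword>(wb_max, W);
  arma::mat col(H * wb_max, kk * C);
  arma::rowvec bt = b.t();

  for (arma::uword n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * H * W * C;
    double* ys = y.begin() + n * H * W * Cout;
    for (arma::uword w0 = 0; w0 < W; w0 += wb_max) {
      const arma::uword wb = std::min(wb_max, W - w0);
      if (col.n_rows != H * wb) col.set_size(H * wb, kk * C);
      im2col_block(xs, H, W, C, col, k, dilation, pad, w0, wb);
      arma::mat yb = col * w;      // (H*wb) x Cout
      yb.each_row() += bt;
      for (arma::uword co = 0; co < Cout; ++co)
        std::memcpy(ys + co * H * W + w0 * H, yb.colptr(co),
                    H * wb * sizeof(double));
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericVector& x, const arma::mat& w,
                    const NumericVector& gy, int k, int dilation) {
  IntegerVector d = dims_of(x);
  const arma::uword H = d[0], W = d[1], C = d[2],
                    N = d.size() > 3 ? d[3] : 1;
  const arma::uword kk = (arma::uword)k * k;
  const arma::uword Cout = w.n_cols;
  const int pad = dilation * (k - 1) / 2;

  NumericVector gx(H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gw(kk * C, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);

  arma::uword wb_max = std::max<arma::uword>(
    1, COL_BLOCK_DOUBLES / std::max<arma::uword>(1, kk * C * H));
  wb_max = std::min<arma::uword>(wb_max, W);
  arma::mat col(H * wb_max, kk * C);

  for (arma::uword n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * H * W * C;
    const double* gys = gy.begin() + n * H * W * Cout;
    double* gxs = gx.begin() + n * H * W * C;
    for (arma::uword w0 = 0; w0 < W; w0 += wb_max) {
      const arma::uword wb = std::min(wb_max, W - w0);
      if (col.n_rows != H * wb) col.set_size(H * wb, kk * C);
      im2col_block(xs, H, W, C, col, k, dilation, pad, w0, wb);

      arma::mat gyb(H * wb, Cout);
      for (arma::uword co = 0; co < Cout; ++co)
        std::memcpy(gyb.colptr(co), gys + co * H * W + w0 * H,
                    H * wb * sizeof(double));
      gw += col.t() * gyb;
      gb += arma::sum(gyb, 0).t();
      arma::mat gcol = gyb * w.t();          // (H*wb) x (kk*C)
      col2im_block(gxs, H, W, C, gcol, k, dilation, pad, w0, wb);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2, over all channel/batch slices.
// idx encodes the argmax corner as di + 2*dj (0..3).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const NumericVector& x) {
  IntegerVector d = dims_of(x);
  const arma::uword H = d[0], W = d[1];
  arma::uword S = 1;
  for (int i = 2; i < d.size(); ++i) S *= d[i];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const arma::uword Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * S);
  IntegerVector idx(Ho * Wo * S);
  IntegerVector od(d.size());
  od[0] = Ho; od[1] = Wo;
  for (int i = 2; i < d.size(); ++i) od[i] = d[i];
  y.attr("dim") = od;
  idx.attr("dim") = od;
  for (arma::uword s = 0; s < S; ++s) {
    const double* xs = x.begin() + s * H * W;
    double* ys = y.begin() + s * Ho * Wo;
    int* is = idx.begin() + s * Ho * Wo;
    for (arma::uword j = 0; j < Wo; ++j) {
      const double* c0 = xs + (2 * j) * H;
      const double* c1 = xs + (2 * j + 1) * H;
      for (arma::uword i = 0; i < Ho; ++i) {
        double best = c0[2 * i];
        int bi = 0;
        if (c0[2 * i + 1] > best) { best = c0[2 * i + 1]; bi = 1; }
        if (c1[2 * i] > best) { best = c1[2 * i]; bi = 2; }
        if (c1[2 * i + 1] > best) { best = c1[2 * i + 1]; bi = 3; }
        ys[j * Ho + i] = best;
        is[j * Ho + i] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(const NumericVector& gy,
                               const IntegerVector& idx) {
  IntegerVector d = dims_of(gy);
  const arma::uword Ho = d[0], Wo = d[1];
  arma::uword S = 1;
  for (int i = 2; i < d.size(); ++i) S *= d[i];
  NumericVector gx(4 * Ho * Wo * S);
  IntegerVector od(d.size());
  od[0] = 2 * Ho; od[1] = 2 * Wo;
  for (int i = 2; i < d.size(); ++i) od[i] = d[i];
  gx.attr("dim") = od;
  const arma::uword H = 2 * Ho;
  for (arma::uword s = 0; s < S; ++s) {
    const double* gys = gy.begin() + s * Ho * Wo;
    const int* is = idx.begin() + s * Ho * Wo;
    double* gxs = gx.begin() + s * 4 * Ho * Wo;
    for (arma::uword j = 0; j < Wo; ++j)
      for (arma::uword i = 0; i < Ho; ++i) {
        const int b = is[j * Ho + i];
        gxs[(2 * j + b / 2) * H + 2 * i + b % 2] += gys[j * Ho + i];
      }
  }
  return gx;
}

struct LinMap { // precomputed 1-D bilinear taps for scale factor 2
  std::vector<arma::uword> i0, i1;
  std::vector<double> w0, w1;
};

static LinMap lin_map(arma::uword n_out, arma::uword n_in) {
  LinMap m;
  m.i0.resize(n_out); m.i1.resize(n_out);
  m.w0.resize(n_out); m.w1.resize(n_out);
  for (arma::uword o = 0; o < n_out; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;   // align_corners = false
    double fl = std::floor(src);
    double t = src - fl;
    long a = (long)fl, bI = a + 1;
    if (a < 0) a = 0;
    if (bI > (long)n_in - 1) bI = n_in - 1;
    if (a > (long)n_in - 1) a = n_in - 1;
    m.i0[o] = (arma::uword)a; m.i1[o] = (arma::uword)bI;
    m.w0[o] = 1.0 - t; m.w1[o] = t;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(const NumericVector& x) {
  IntegerVector d = dims_of(x);
  const arma::uword H = d[0], W = d[1];
  arma::uword S = 1;
  for (int i = 2; i < d.size(); ++i) S *= d[i];
  LinMap mh = lin_map(2 * H, H), mw = lin_map(2 * W, W);
  NumericVector y(4 * H * W * S);
  IntegerVector od(d.size());
  od[0] = 2 * H; od[1] = 2 * W;
  for (int i = 2; i < d.size(); ++i) od[i] = d[i];
  y.attr("dim") = od;
  for (arma::uword s = 0; s < S; ++s) {
    const double* xs = x.begin() + s * H * W;
    double* ys = y.begin() + s * 4 * H * W;
    for (arma::uword j = 0; j < 2 * W; ++j) {
      const double* ca = xs + mw.i0[j] * H;
      const double* cb = xs + mw.i1[j] * H;
      const double wa = mw.w0[j], wb = mw.w1[j];
      double* yc = ys + j * 2 * H;
      for (arma::uword i = 0; i < 2 * H; ++i) {
        yc[i] = mh.w0[i] * (wa * ca[mh.i0[i]] + wb * cb[mh.i0[i]]) +
                mh.w1[i] * (wa * ca[mh.i1[i]] + wb * cb[mh.i1[i]]);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(const NumericVector& gy) {
  IntegerVector d = dims_of(gy);
  const arma::uword Ho = d[0], Wo = d[1];
  arma::uword S = 1;
  for (int i = 2; i < d.size(); ++i) S *= d[i];
  const arma::uword H = Ho / 2, W = Wo / 2;
  LinMap mh = lin_map(Ho, H), mw = lin_map(Wo, W);
  NumericVector gx(H * W * S);
  IntegerVector od(d.size());
  od[0] = H; od[1] = W;
  for (int i = 2; i < d.size(); ++i) od[i] = d[i];
  gx.attr("dim") = od;
  for (arma::uword s = 0; s < S; ++s) {
    const double* gys = gy.begin() + s * Ho * Wo;
    double* gxs = gx.begin() + s * H * W;
    for (arma::uword j = 0; j < Wo; ++j) {
      double* ca = gxs + mw.i0[j] * H;
      double* cb = gxs + mw.i1[j] * H;
      const double wa = mw.w0[j], wb = mw.w1[j];
      const double* gc = gys + j * Ho;
      for (arma::uword i = 0; i < Ho; ++i) {
        const double g0 = mh.w0[i] * gc[i], g1 = mh.w1[i] * gc[i];
        ca[mh.i0[i]] += wa * g0;
        cb[mh.i0[i]] += wb * g0;
        ca[mh.i1[i]] += wa * g1;
        cb[mh.i1[i]] += wb * g1;
      }
    }
  }
  return gx;
}
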