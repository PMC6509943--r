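// Hot kernels of the dual-CNN engine: stride-1 valid cross-correlation and
// stride-1 overlapping max pooling, forward and backward, batched over the
// trailing array dimension. Convolutions are lowered to a single GEMM per
// call via im2col; the filter bank (f, c, kh, kw) reinterprets in place as
// the (f, c*kh*kw) kernel matrix because both are column-major. A border
// of zeros (the "pad zeros around" step before every convolution) is
// applied implicitly inside im2col, so padded tensors are never
// materialized; the im2col matrix built in the forward pass is returned to
// R and fed back to the backward pass, which therefore never rebuilds it.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill `cols` (c*kh*kw, hout*wout*B) from input (c, h, w, B), viewing the
// input with a one-cell zero border when pad is true. Column = spatial
// position (i fastest, then j, then batch); row = (cc, u, v), cc fastest.
// (c, h) are the two fastest input dimensions, so rows i..i+kh-1 of all c
// channels are contiguous and copy with one memcpy per (v, position).
static void fill_im2col(double* out, const double* x, int c, int h, int w,
                        int B, int kh, int kw, bool pad) {
  const int hp = pad ? h + 2 : h, wp = pad ? w + 2 : w;
  const int hout = hp - kh + 1, wout = wp - kw + 1;
  const int off = pad ? 1 : 0;
  const arma::uword crows = (arma::uword)c * kh * kw;
  for (int n = 0; n < B; ++n) {
    const double* xb = x + (arma::uword)n * c * h * w;
    for (int j = 0; j < wout; ++j) {
      for (int i = 0; i < hout; ++i) {
        double* col = out + crows * ((arma::uword)i + (arma::uword)hout * (j + (arma::uword)wout * n));
        for (int v = 0; v < kw; ++v) {
          const int jj = j + v - off;            // source column (unpadded)
          double* dst = col + (arma::uword)c * kh * v;
          if (jj < 0 || jj >= w) {
            std::memset(dst, 0, sizeof(double) * c * kh);
            continue;
          }
          const int i0 = i - off;                // first source row
          int u0 = 0, u1 = kh;                   // clip row range to [0, h)
          if (i0 < 0) u0 = -i0;
          if (i0 + kh > h) u1 = h - i0;
          if (u0 > 0) std::memset(dst, 0, sizeof(double) * c * u0);
          if (u1 < kh) std::memset(dst + (arma::uword)c * u1, 0,
                                   sizeof(double) * c * (kh - u1));
          if (u1 > u0)
            std::memcpy(dst + (arma::uword)c * u0,
                        xb + (arma::uword)c * ((i0 + u0) + (arma::uword)h * jj),
                        sizeof(double) * c * (u1 - u0));
        }
      }
    }
  }
}

// Forward convolution. Returns Z (f, hout, wout, B) and the im2col matrix
// for the backward pass.
// [[Rcpp::export]]
List cpp_conv_fwd(NumericVector X, IntegerVector xdim,
                  NumericVector W, IntegerVector wdim,
                  NumericVector b, bool relu, bool pad) {
  const int c = xdim[0], h = xdim[1], w = xdim[2], B = xdim[3];
  const int f = wdim[0], kh = wdim[2], kw = wdim[3];
  const int hp = pad ? h + 2 : h, wp = pad ? w + 2 : w;
  const int hout = hp - kh + 1, wout = wp - kw + 1;
  if (hout < 1 || wout < 1) stop("conv: kernel larger than input");
  if (wdim[1] != c) stop("conv: channel mismatch");
  const arma::uword crows = (arma::uword)c * kh * kw;
  const arma::uword N = (arma::uword)hout * wout * B;
  NumericMatrix colsR((int)crows, (int)N);
  fill_im2col(colsR.begin(), X.begin(), c, h, w, B, kh, kw, pad);
  const arma::mat cols(colsR.begin(), crows, N, false, true);
  const arma::mat Wm(const_cast<double*>(W.begin()), f, crows, false, true);
  arma::mat Z = Wm * cols;
  Z.each_col() += arma::vec(b.begin(), f);
  if (relu) Z.transform([](double z) { return z > 0 ? z : 0.0; });
  NumericVector out(Z.begin(), Z.end());
  out.attr("dim") = IntegerVector::create(f, hout, wout, B);
  return List::create(_["Z"] = out, _["cols"] = colsR);
}

// Backward: `cols` is the forward's im2col matrix; dZ the upstream
// gradient (f, hout, wout, B); Zpost the forward output (positivity = relu
// mask). Returns dX on the *unpadded* input geometry, plus dW, db.
// [[Rcpp::export]]
List cpp_conv_bwd(NumericMatrix cols, IntegerVector xdim,
                  NumericVector W, IntegerVector wdim,
                  NumericVector dZ, NumericVector Zpost, bool relu,
                  bool pad) {
  const int c = xdim[0], h = xdim[1], w = xdim[2], B = xdim[3];
  const int f = wdim[0], kh = wdim[2], kw = wdim[3];
  const int hp = pad ? h + 2 : h, wp = pad ? w + 2 : w;
  const int hout = hp - kh + 1, wout = wp - kw + 1;
  const int off = pad ? 1 : 0;
  const arma::uword crows = (arma::uword)c * kh * kw;
  const arma::uword N = (arma::uword)hout * wout * B;

  arma::mat dZm(dZ.begin(), f, N); // copy (mutated by the relu mask)
  if (relu) {
    const double* zp = Zpost.begin();
    double* dz = dZm.memptr();
    const arma::uword tot = (arma::uword)f * N;
    for (arma::uword k = 0; k < tot; ++k)
      if (zp[k] <= 0) dz[k] = 0.0;
  }
  arma::vec db = arma::sum(dZm, 1);
  const arma::mat colsA(cols.begin(), crows, N, false, true);
  arma::mat dW = dZm * colsA.t();                // (f, c*kh*kw)
  const arma::mat Wm(const_cast<double*>(W.begin()), f, crows, false, true);
  arma::mat dcols = Wm.t() * dZm;                // (c*kh*kw, N)

  // col2im scatter-add back onto the unpadded geometry
  NumericVector dX((arma::uword)c * h * w * B);
  double* dx = dX.begin();
  const double* dc = dcols.memptr();
  for (int n = 0; n < B; ++n) {
    double* xb = dx + (arma::uword)n * c * h * w;
    for (int j = 0; j < wout; ++j) {
      for (int i = 0; i < hout; ++i) {
        const double* col = dc + crows * ((arma::uword)i + (arma::uword)hout * (j + (arma::uword)wout * n));
        for (int v = 0; v < kw; ++v) {
          const int jj = j + v - off;
          if (jj < 0 || jj >= w) continue;
          const int i0 = i - off;
          int u0 = 0, u1 = kh;
          if (i0 < 0) u0 = -i0;
          if (i0 + kh > h) u1 = h - i0;
          double* dst = xb + (arma::uword)c * ((i0 + u0) + (arma::uword)h * jj);
          const double* src = col + (arma::uword)c * (kh * v + u0);
          const int len = c * (u1 - u0);
          for (int k = 0; k < len; ++k) dst[k] += src[k];
        }
      }
    }
  }
  dX.attr("dim") = xdim;
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = wdim;
  return List::create(_["dX"] = dX, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Stride-1 max pooling with argmax capture; ties go to the first position
// in scan order (rows within a window first), fixing a deterministic
// subgradient for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector X, IntegerVector xdim, int ng, int np) {
  const int c = xdim[0], h = xdim[1], w = xdim[2], B = xdim[3];
  const int hout = h - ng + 1, wout = w - np + 1;
  if (hout < 1 || wout < 1) stop("maxpool: window larger than input");
  const arma::uword nout = (arma::uword)c * hout * wout * B;
  NumericVector out(nout);
  IntegerVector arg(nout); // 0-based linear index into X
  const double* x = X.begin();
  double* o = out.begin();
  int* a = arg.begin();
  arma::uword q = 0;
  for (int n = 0; n < B; ++n) {
    const arma::uword nb = (arma::uword)n * c * h * w;
    for (int j = 0; j < wout; ++j) {
      for (int i = 0; i < hout; ++i) {
        for (int k = 0; k < c; ++k, ++q) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword besti = 0;
          for (int v = 0; v < np; ++v) {
            for (int u = 0; u < ng; ++u) {
              const arma::uword idx = nb + k + (arma::uword)c * ((i + u) + (arma::uword)h * (j + v));
              if (x[idx] > best) { best = x[idx]; besti = idx; }
            }
          }
          o[q] = best;
          a[q] = (int)besti;
        }
      }
    }
  }
  // q advances with k innermost, then i, j, n: column-major (c, hout,
  // wout, B) order, matching the dim attribute below.
  out.attr("dim") = IntegerVector::create(c, hout, wout, B);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dOut, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector dX((arma::uword)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double* dx = dX.begin();
  const double* d = dOut.begin();
  const int* a = argmax.begin();
  const arma::uword n = dOut.size();
  for (arma::uword q = 0; q < n; ++q) dx[a[q]] += d[q];
  dX.attr("dim") = xdim;
  return dX;
}
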