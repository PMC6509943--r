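// Persistent training engine: the full forward + backward pass of the
// dual-CNN scorer over a minibatch, with every intermediate buffer
// preallocated once per (shape, batch-capacity) so a training step
// performs no memory allocation. The slower kernel-by-kernel path
// (kernels.cpp) backs the public single-sample R API; the test suite
// checks the two paths against each other and against finite differences.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

typedef arma::uword uw;

// ---- convolution layer (implicit one-cell zero border) ---------------------
// The per-filter bias rides inside the GEMM as a constant ones-row of the
// im2col matrix, so the raw GEMM output already includes it; relu is
// deferred to the pooling stage (relu and max commute), and the backward
// relu mask tests the raw pre-activations.
struct ConvLayer {
  int c, h, w, f, kh, kw;          // unpadded input geometry, filters, kernel
  int hp, wp, hout, wout;
  bool need_dX;
  arma::mat cols, dcols, Z, dWfull, Waug;
  arma::vec dX;

  void init(int c_, int h_, int w_, int f_, int kh_, int kw_, int Bcap,
            bool need_dX_) {
    c = c_; h = h_; w = w_; f = f_; kh = kh_; kw = kw_;
    hp = h + 2; wp = w + 2;
    hout = hp - kh + 1; wout = wp - kw + 1;
    need_dX = need_dX_;
    const uw crows = (uw)c * kh * kw, N = (uw)hout * wout * Bcap;
    cols.set_size(crows + 1, N);
    cols.row(crows).ones();        // constant bias row, never overwritten
    dcols.set_size(crows, N);
    Z.set_size(f, N);
    dWfull.set_size(f, crows + 1);
    Waug.set_size(f, crows + 1);
    if (need_dX) dX.set_size((uw)c * h * w * Bcap);
  }

  void im2col(const double* x, int B) {
    const uw crows = (uw)c * kh * kw;
    const uw ld = crows + 1;       // leading dimension (bias row at bottom)
    double* out = cols.memptr();
    for (int n = 0; n < B; ++n) {
      const double* xb = x + (uw)n * c * h * w;
      for (int j = 0; j < wout; ++j) {
        for (int i = 0; i < hout; ++i) {
          double* col = out + ld * ((uw)i + (uw)hout * (j + (uw)wout * n));
          for (int v = 0; v < kw; ++v) {
            const int jj = j + v - 1;
            double* dst = col + (uw)c * kh * v;
            if (jj < 0 || jj >= w) { std::memset(dst, 0, sizeof(double) * c * kh); continue; }
            const int i0 = i - 1;
            int u0 = 0, u1 = kh;
            if (i0 < 0) u0 = -i0;
            if (i0 + kh > h) u1 = h - i0;
            if (u0 > 0) std::memset(dst, 0, sizeof(double) * c * u0);
            if (u1 < kh) std::memset(dst + (uw)c * u1, 0, sizeof(double) * c * (kh - u1));
            if (u1 > u0)
              std::memcpy(dst + (uw)c * u0,
                          xb + (uw)c * ((i0 + u0) + (uw)h * jj),
                          sizeof(double) * c * (u1 - u0));
          }
        }
      }
    }
  }

  // x: (c, h, w, B); Wp: (f, c*kh*kw); bp: (f). Z holds raw pre-activations
  // (bias included); relu is applied downstream by the pooling clamp.
  void fwd(const double* x, const double* Wp, const double* bp, int B) {
    const uw crows = (uw)c * kh * kw, N = (uw)hout * wout * B;
    im2col(x, B);
    std::memcpy(Waug.memptr(), Wp, sizeof(double) * f * crows);
    std::memcpy(Waug.memptr() + (uw)f * crows, bp, sizeof(double) * f);
    arma::mat Zv(Z.memptr(), f, N, false, true);
    const arma::mat Cv(cols.memptr(), crows + 1, N, false, true);
    Zv = Waug * Cv;
  }

  // dzup: (f, hout*wout*B), mutated in place by the relu mask; produces
  // dWfull (weights | bias) and, if need_dX, dX on the unpadded geometry.
  void bwd(const double* Wp, double* dzup, int B) {
    const uw crows = (uw)c * kh * kw, N = (uw)hout * wout * B;
    {
      const double* zp = Z.memptr();
      const uw tot = (uw)f * N;
      for (uw k = 0; k < tot; ++k) if (zp[k] <= 0) dzup[k] = 0.0;
    }
    arma::mat dZv(dzup, f, N, false, true);
    const arma::mat Cv(cols.memptr(), crows + 1, N, false, true);
    arma::mat dWv(dWfull.memptr(), f, crows + 1, false, true);
    dWv = dZv * Cv.t();            // last column is the bias gradient
    if (!need_dX) return;
    const arma::mat Wm(const_cast<double*>(Wp), f, crows, false, true);
    arma::mat dCv(dcols.memptr(), crows, N, false, true);
    dCv = Wm.t() * dZv;
    // col2im onto the unpadded geometry
    std::memset(dX.memptr(), 0, sizeof(double) * (uw)c * h * w * B);
    double* dx = dX.memptr();
    const double* dc = dcols.memptr();
    for (int n = 0; n < B; ++n) {
      double* xb = dx + (uw)n * c * h * w;
      for (int j = 0; j < wout; ++j) {
        for (int i = 0; i < hout; ++i) {
          const double* col = dc + crows * ((uw)i + (uw)hout * (j + (uw)wout * n));
          for (int v = 0; v < kw; ++v) {
            const int jj = j + v - 1;
            if (jj < 0 || jj >= w) continue;
            const int i0 = i - 1;
            int u0 = 0, u1 = kh;
            if (i0 < 0) u0 = -i0;
            if (i0 + kh > h) u1 = h - i0;
            double* dst = xb + (uw)c * ((i0 + u0) + (uw)h * jj);
            const double* src = col + (uw)c * (kh * v + u0);
            const int len = c * (u1 - u0);
            for (int k = 0; k < len; ++k) dst[k] += src[k];
          }
        }
      }
    }
  }
};

// ---- stride-1 max pooling ---------------------------------------------------
struct PoolLayer {
  int c, h, w, ng, np, hout, wout;
  arma::vec out, dX;
  std::vector<int64_t> arg;        // 0-based linear index into input

  void init(int c_, int h_, int w_, int ng_, int np_, int Bcap) {
    c = c_; h = h_; w = w_; ng = ng_; np = np_;
    hout = h - ng + 1; wout = w - np + 1;
    out.set_size((uw)c * hout * wout * Bcap);
    arg.resize((uw)c * hout * wout * Bcap);
    dX.set_size((uw)c * h * w * Bcap);
  }

  // contiguous-run sweep; ties keep the first candidate in the
  // (u fastest, then v) scan order, matching cpp_maxpool_fwd
  void fwd(const double* x, int B) {
    const int runlen = c * hout;
    double* __restrict o = out.memptr();
    int64_t* __restrict a = arg.data();
    for (int n = 0; n < B; ++n) {
      const uw nb = (uw)n * c * h * w;
      for (int j = 0; j < wout; ++j) {
        double* __restrict orun = o + (uw)runlen * (j + (uw)wout * n);
        int64_t* __restrict arun = a + (uw)runlen * (j + (uw)wout * n);
        bool first = true;
        for (int v = 0; v < np; ++v) {
          for (int u = 0; u < ng; ++u) {
            const uw src = nb + (uw)c * (u + (uw)h * (j + v));
            const double* __restrict xr = x + src;
            if (first) {
              for (int t = 0; t < runlen; ++t) { orun[t] = xr[t] > 0 ? xr[t] : 0.0; arun[t] = (int64_t)(src + t); }
              first = false;
            } else {
              // branchless select so the loop vectorizes
              for (int t = 0; t < runlen; ++t) {
                const bool gt = xr[t] > orun[t];
                orun[t] = gt ? xr[t] : orun[t];
                arun[t] = gt ? (int64_t)(src + t) : arun[t];
              }
            }
          }
        }
      }
    }
  }

  void bwd(const double* dout, int B) {
    const uw nin = (uw)c * h * w * B, nout = (uw)c * hout * wout * B;
    std::memset(dX.memptr(), 0, sizeof(double) * nin);
    double* dx = dX.memptr();
    const int64_t* a = arg.data();
    for (uw q = 0; q < nout; ++q) dx[a[q]] += dout[q];
  }
};

// ---- the engine -------------------------------------------------------------
struct Engine {
  int n_l, n_d, n_m, n_t, n_max, ah, C, Bcap;
  int zdim, wcon;
  bool bwd_ready;

  ConvLayer conv1, conv2, convA, convF;
  PoolLayer pool1, pool2, poolA, poolF;

  arma::vec Zc, dZglo, dZatt;      // concatenation buffer and its splits
  arma::mat maskm;                 // (n_max, 6) validity mask, 0/1
  // attention forward buffers (columns = 6 * Bcap)
  arma::mat T1, S, alpha, Yv, T2, logits, p;
  arma::mat sR, beta;              // (6, Bcap)
  arma::mat g, dg;                 // (n_max, Bcap)
  // attention backward buffers
  arma::mat dYv, dalpha, dS, dT1, dpre2;
  arma::mat dH_F, dW_xF, dW_yR, dh_R;
  arma::vec db_F, db_R;
  arma::mat dbeta, dsR;
  arma::mat dlogits, dW_out, dzo;
  arma::vec db_o;

  void init(int n_l_, int n_d_, int n_m_, int nw, int nf, int ng, int np,
            int f1, int f2, int fa, int ff, int ah_, int Bcap_) {
    n_l = n_l_; n_d = n_d_; n_m = n_m_;
    n_t = n_l + n_d + n_m;
    n_max = std::max(n_l, std::max(n_d, n_m));
    ah = ah_; C = 2; Bcap = Bcap_;
    bwd_ready = false;

    conv1.init(1, 2, n_t, f1, nw, nf, Bcap, false);
    pool1.init(f1, conv1.hout, conv1.wout, ng, np, Bcap);
    conv2.init(f1, pool1.hout, pool1.wout, f2, nw, nf, Bcap, true);
    pool2.init(f2, conv2.hout, conv2.wout, ng, np, Bcap);
    convA.init(1, 1, n_max, fa, nw, nf, Bcap, true);
    poolA.init(fa, convA.hout, convA.wout, ng, np, Bcap);
    // concatenation width = global branch width (Z_att right-padded to it)
    wcon = pool2.wout;
    if (poolA.wout > wcon) stop("attention representation wider than the global one");
    convF.init(f2, pool2.hout + poolA.hout, wcon, ff, nw, nf, Bcap, true);
    poolF.init(ff, convF.hout, convF.wout, ng, np, Bcap);
    zdim = ff * poolF.hout * poolF.wout;

    Zc.set_size((uw)convF.c * convF.h * wcon * Bcap);
    dZglo.set_size((uw)pool2.c * pool2.hout * pool2.wout * Bcap);
    dZatt.set_size((uw)poolA.c * poolA.hout * poolA.wout * Bcap);

    maskm.zeros(n_max, 6);
    for (int i = 0; i < n_l; ++i) { maskm(i, 0) = 1; maskm(i, 1) = 1; }
    for (int i = 0; i < n_d; ++i) { maskm(i, 2) = 1; maskm(i, 3) = 1; }
    for (int i = 0; i < n_m; ++i) { maskm(i, 4) = 1; maskm(i, 5) = 1; }

    const int n6 = 6 * Bcap;
    T1.set_size(ah, n6); S.set_size(n_max, n6); alpha.set_size(n_max, n6);
    Yv.set_size(n_max, n6); T2.set_size(ah, n6);
    sR.set_size(6, Bcap); beta.set_size(6, Bcap);
    g.set_size(n_max, Bcap); dg.set_size(n_max, Bcap);
    logits.set_size(C, Bcap); p.set_size(C, Bcap);
    dYv.set_size(n_max, n6); dalpha.set_size(n_max, n6); dS.set_size(n_max, n6);
    dT1.set_size(ah, n6); dpre2.set_size(ah, n6);
    dH_F.set_size(n_max, ah); dW_xF.set_size(ah, n_max);
    dW_yR.set_size(ah, n_max); dh_R.set_size(1, ah);
    db_F.set_size(ah); db_R.set_size(ah);
    dbeta.set_size(6, Bcap); dsR.set_size(6, Bcap);
    dlogits.set_size(C, Bcap); dW_out.set_size(C, zdim);
    dzo.set_size(zdim, Bcap); db_o.set_size(C);
  }

  const double* par(const List& params, const char* nm, arma::vec& hold) {
    NumericVector v = params[nm];
    hold = arma::vec(v.begin(), v.size(), false, true);
    return v.begin();
  }

  // forward over B samples; fills p (C, B)
  void forward(const double* P2, const double* Xa, const List& params, int B) {
    NumericVector W1 = params["W_conv1"], b1 = params["b_conv1"];
    NumericVector W2 = params["W_conv2"], b2 = params["b_conv2"];
    NumericVector WxF = params["W_xF"], bF = params["b_F"], HF = params["H_F"];
    NumericVector WyR = params["W_yR"], bR = params["b_R"], hR = params["h_R"];
    NumericVector Wa = params["W_attconv"], ba = params["b_attconv"];
    NumericVector Wf = params["W_fin"], bf = params["b_fin"];
    NumericVector Wout = params["W_out"], bo = params["b_o"];

    conv1.fwd(P2, W1.begin(), b1.begin(), B);
    pool1.fwd(conv1.Z.memptr(), B);
    conv2.fwd(pool1.out.memptr(), W2.begin(), b2.begin(), B);
    pool2.fwd(conv2.Z.memptr(), B);

    // attention
    const int n6 = 6 * B;
    const arma::mat Xm(const_cast<double*>(Xa), n_max, n6, false, true);
    const arma::mat WxFm(WxF.begin(), ah, n_max, false, true);
    const arma::mat HFm(HF.begin(), n_max, ah, false, true);
    const arma::mat WyRm(WyR.begin(), ah, n_max, false, true);
    const arma::mat hRm(hR.begin(), 1, ah, false, true);
    arma::mat T1v(T1.memptr(), ah, n6, false, true);
    arma::mat Sv(S.memptr(), n_max, n6, false, true);
    arma::mat alphav(alpha.memptr(), n_max, n6, false, true);
    arma::mat Yvv(Yv.memptr(), n_max, n6, false, true);
    arma::mat T2v(T2.memptr(), ah, n6, false, true);

    T1v = WxFm * Xm;
    T1v.each_col() += arma::vec(bF.begin(), ah);
    T1v = arma::tanh(T1v);
    Sv = HFm * T1v;
    // masked softmax per column
    for (int t = 0; t < n6; ++t) {
      const double* mk = maskm.colptr(t % 6);
      double* sc = Sv.colptr(t);
      double mx = -std::numeric_limits<double>::infinity();
      for (int i = 0; i < n_max; ++i) if (mk[i] > 0 && sc[i] > mx) mx = sc[i];
      double se = 0;
      for (int i = 0; i < n_max; ++i) {
        double e = mk[i] > 0 ? std::exp(sc[i] - mx) : 0.0;
        alphav(i, t) = e; se += e;
      }
      for (int i = 0; i < n_max; ++i) alphav(i, t) /= se;
    }
    Yvv = alphav % Xm;
    T2v = WyRm * Yvv;
    T2v.each_col() += arma::vec(bR.begin(), ah);
    T2v = arma::tanh(T2v);
    {
      arma::rowvec s = hRm * T2v;    // (1, 6B)
      for (int n = 0; n < B; ++n) {
        double mx = -std::numeric_limits<double>::infinity();
        for (int i = 0; i < 6; ++i) { sR(i, n) = s[6 * n + i]; if (sR(i, n) > mx) mx = sR(i, n); }
        double se = 0;
        for (int i = 0; i < 6; ++i) { beta(i, n) = std::exp(sR(i, n) - mx); se += beta(i, n); }
        for (int i = 0; i < 6; ++i) beta(i, n) /= se;
        // g = sum_i beta_i y_i
        double* gp = g.colptr(n);
        std::memset(gp, 0, sizeof(double) * n_max);
        for (int i = 0; i < 6; ++i) {
          const double bi = beta(i, n);
          const double* yp = Yvv.colptr(6 * n + i);
          for (int k = 0; k < n_max; ++k) gp[k] += bi * yp[k];
        }
      }
    }
    convA.fwd(g.memptr(), Wa.begin(), ba.begin(), B);
    poolA.fwd(convA.Z.memptr(), B);

    // concatenate Z_glo over Z_att (right-padded to width n_t)
    {
      const int cch = convF.c;               // channels (= f2)
      const int rows = convF.h;              // pool2.hout + poolA.hout
      const int rg = pool2.hout;             // global rows
      double* zc = Zc.memptr();
      const double* zg = pool2.out.memptr();
      const double* za = poolA.out.memptr();
      std::memset(zc, 0, sizeof(double) * (uw)cch * rows * wcon * B);
      for (int n = 0; n < B; ++n) {
        for (int t = 0; t < wcon; ++t) {
          double* dst = zc + (uw)cch * rows * (t + (uw)wcon * n);
          const double* sg = zg + (uw)cch * rg * (t + (uw)wcon * n);
          std::memcpy(dst, sg, sizeof(double) * cch * rg);
          if (t < poolA.wout) {
            const double* sa = za + (uw)cch * 1 * (t + (uw)poolA.wout * n);
            std::memcpy(dst + (uw)cch * rg, sa, sizeof(double) * cch);
          }
        }
      }
    }
    convF.fwd(Zc.memptr(), Wf.begin(), bf.begin(), B);
    poolF.fwd(convF.Z.memptr(), B);

    // output layer
    const arma::mat Woutm(Wout.begin(), C, zdim, false, true);
    const arma::mat zo(poolF.out.memptr(), zdim, B, false, true);
    arma::mat lg(logits.memptr(), C, B, false, true);
    lg = Woutm * zo;
    lg.each_col() += arma::vec(bo.begin(), C);
    for (int n = 0; n < B; ++n) {
      double mx = std::max(lg(0, n), lg(1, n));
      double e0 = std::exp(lg(0, n) - mx), e1 = std::exp(lg(1, n) - mx);
      p(0, n) = e0 / (e0 + e1);
      p(1, n) = e1 / (e0 + e1);
    }
  }

  // backward; Zl = one-hot labels (C, B); returns summed CE loss
  double backward(const double* P2, const double* Xa, const List& params,
                  const double* Zl, int B) {
    NumericVector W2 = params["W_conv2"];
    NumericVector WxF = params["W_xF"], HF = params["H_F"];
    NumericVector WyR = params["W_yR"], hR = params["h_R"];
    NumericVector Wa = params["W_attconv"];
    NumericVector Wf = params["W_fin"];
    NumericVector Wout = params["W_out"];
    NumericVector W1 = params["W_conv1"];

    double loss = 0;
    for (int n = 0; n < B; ++n) {
      for (int k = 0; k < C; ++k) {
        if (Zl[k + C * n] == 1) {
          double pk = p(k, n);
          loss -= std::log(pk < 1e-12 ? 1e-12 : pk);
        }
        dlogits(k, n) = p(k, n) - Zl[k + C * n];
      }
    }
    const arma::mat zo(poolF.out.memptr(), zdim, B, false, true);
    arma::mat dlg(dlogits.memptr(), C, B, false, true);
    arma::mat dWoutv(dW_out.memptr(), C, zdim, false, true);
    dWoutv = dlg * zo.t();
    db_o = arma::sum(dlg, 1);
    const arma::mat Woutm(Wout.begin(), C, zdim, false, true);
    arma::mat dzov(dzo.memptr(), zdim, B, false, true);
    dzov = Woutm.t() * dlg;

    poolF.bwd(dzo.memptr(), B);
    convF.bwd(Wf.begin(), poolF.dX.memptr(), B);

    // split dZc into global and attention parts
    {
      const int cch = convF.c, rows = convF.h, rg = pool2.hout;
      const double* dzc = convF.dX.memptr();
      double* dzg = dZglo.memptr();
      double* dza = dZatt.memptr();
      std::memset(dza, 0, sizeof(double) * (uw)cch * poolA.wout * B);
      for (int n = 0; n < B; ++n) {
        for (int t = 0; t < wcon; ++t) {
          const double* src = dzc + (uw)cch * rows * (t + (uw)wcon * n);
          std::memcpy(dzg + (uw)cch * rg * (t + (uw)wcon * n), src,
                      sizeof(double) * cch * rg);
          if (t < poolA.wout)
            std::memcpy(dza + (uw)cch * (t + (uw)poolA.wout * n),
                        src + (uw)cch * rg, sizeof(double) * cch);
        }
      }
    }

    // attention branch
    poolA.bwd(dZatt.memptr(), B);
    convA.bwd(Wa.begin(), poolA.dX.memptr(), B);
    {
      const int n6 = 6 * B;
      const arma::mat Xm(const_cast<double*>(Xa), n_max, n6, false, true);
      const arma::mat WxFm(WxF.begin(), ah, n_max, false, true);
      const arma::mat HFm(HF.begin(), n_max, ah, false, true);
      const arma::mat WyRm(WyR.begin(), ah, n_max, false, true);
      const arma::mat hRm(hR.begin(), 1, ah, false, true);
      arma::mat T1v(T1.memptr(), ah, n6, false, true);
      arma::mat alphav(alpha.memptr(), n_max, n6, false, true);
      arma::mat Yvv(Yv.memptr(), n_max, n6, false, true);
      arma::mat T2v(T2.memptr(), ah, n6, false, true);
      arma::mat dYvv(dYv.memptr(), n_max, n6, false, true);
      arma::mat dalphav(dalpha.memptr(), n_max, n6, false, true);
      arma::mat dSv(dS.memptr(), n_max, n6, false, true);
      arma::mat dT1v(dT1.memptr(), ah, n6, false, true);
      arma::mat dpre2v(dpre2.memptr(), ah, n6, false, true);

      // dg is convA.dX: (1, 1, n_max, B) = (n_max, B)
      const double* dgp = convA.dX.memptr();
      // g = sum_i beta_i y_i
      for (int n = 0; n < B; ++n) {
        const double* dgc = dgp + (uw)n_max * n;
        for (int i = 0; i < 6; ++i) {
          const double bi = beta(i, n);
          double* dy = dYvv.colptr(6 * n + i);
          const double* yp = Yvv.colptr(6 * n + i);
          double acc = 0;
          for (int k = 0; k < n_max; ++k) {
            dy[k] = bi * dgc[k];
            acc += yp[k] * dgc[k];
          }
          dbeta(i, n) = acc;
        }
        // softmax over the 6 relationships
        double dot = 0;
        for (int i = 0; i < 6; ++i) dot += beta(i, n) * dbeta(i, n);
        for (int i = 0; i < 6; ++i) dsR(i, n) = beta(i, n) * (dbeta(i, n) - dot);
      }
      // s^R = h_R tanh(W_yR y + b_R)
      arma::rowvec dsRrow(6 * B);
      for (int n = 0; n < B; ++n)
        for (int i = 0; i < 6; ++i) dsRrow[6 * n + i] = dsR(i, n);
      arma::mat dhRv(dh_R.memptr(), 1, ah, false, true);
      dhRv = dsRrow * T2v.t();
      dpre2v = hRm.t() * dsRrow;               // dT2
      dpre2v %= (1.0 - T2v % T2v);
      arma::mat dWyRv(dW_yR.memptr(), ah, n_max, false, true);
      dWyRv = dpre2v * Yvv.t();
      db_R = arma::sum(dpre2v, 1);
      dYvv += WyRm.t() * dpre2v;
      // y = alpha * x ; masked softmax over positions
      dalphav = dYvv % Xm;
      for (int t = 0; t < n6; ++t) {
        double dot = 0;
        for (int i = 0; i < n_max; ++i) dot += alphav(i, t) * dalphav(i, t);
        for (int i = 0; i < n_max; ++i)
          dSv(i, t) = alphav(i, t) * (dalphav(i, t) - dot);
      }
      arma::mat dHFv(dH_F.memptr(), n_max, ah, false, true);
      dHFv = dSv * T1v.t();
      dT1v = HFm.t() * dSv;
      dT1v %= (1.0 - T1v % T1v);
      arma::mat dWxFv(dW_xF.memptr(), ah, n_max, false, true);
      dWxFv = dT1v * Xm.t();
      db_F = arma::sum(dT1v, 1);
    }

    // left branch
    pool2.bwd(dZglo.memptr(), B);
    conv2.bwd(W2.begin(), pool2.dX.memptr(), B);
    pool1.bwd(conv2.dX.memptr(), B);
    conv1.bwd(W1.begin(), pool1.dX.memptr(), B);
    return loss;
  }
};

// [[Rcpp::export]]
SEXP cpp_engine_create(int n_l, int n_d, int n_m, List cfg, int Bcap) {
  Engine* e = new Engine();
  e->init(n_l, n_d, n_m,
          as<int>(cfg["n_w"]), as<int>(cfg["n_f"]),
          as<int>(cfg["n_g"]), as<int>(cfg["n_p"]),
          as<int>(cfg["n_conv1"]), as<int>(cfg["n_conv2"]),
          as<int>(cfg["n_att_conv"]), as<int>(cfg["n_final"]),
          as<int>(cfg["attention_hidden"]), Bcap);
  XPtr<Engine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export]]
NumericMatrix cpp_engine_forward(SEXP eptr, NumericVector P2, NumericVector Xa,
                                 List params, int B) {
  XPtr<Engine> e(eptr);
  if (B > e->Bcap) stop("batch exceeds engine capacity");
  e->forward(P2.begin(), Xa.begin(), params, B);
  NumericMatrix out(e->C, B);
  std::memcpy(out.begin(), e->p.memptr(), sizeof(double) * e->C * B);
  return out;
}

// [[Rcpp::export]]
List cpp_engine_step(SEXP eptr, NumericVector P2, NumericVector Xa,
                     List params, NumericMatrix Zlab, int B) {
  XPtr<Engine> e(eptr);
  if (B > e->Bcap) stop("batch exceeds engine capacity");
  e->forward(P2.begin(), Xa.begin(), params, B);
  double loss = e->backward(P2.begin(), Xa.begin(), params, Zlab.begin(), B);

  auto vec = [](const arma::vec& v) { return NumericVector(v.begin(), v.end()); };
  auto mat = [](const arma::mat& m, IntegerVector d) {
    NumericVector out(m.begin(), m.end());
    out.attr("dim") = d;
    return out;
  };
  // split a conv layer's (weights | bias) gradient block
  auto convW = [&mat](const ConvLayer& cl) {
    const arma::uword crows = (arma::uword)cl.c * cl.kh * cl.kw;
    return mat(cl.dWfull.cols(0, crows - 1),
               IntegerVector::create(cl.f, cl.c, cl.kh, cl.kw));
  };
  auto convB = [](const ConvLayer& cl) {
    const arma::uword crows = (arma::uword)cl.c * cl.kh * cl.kw;
    arma::vec b = cl.dWfull.col(crows);
    return NumericVector(b.begin(), b.end());
  };
  List g = List::create(
    _["W_conv1"] = convW(e->conv1),
    _["b_conv1"] = convB(e->conv1),
    _["W_conv2"] = convW(e->conv2),
    _["b_conv2"] = convB(e->conv2),
    _["W_xF"] = mat(e->dW_xF, IntegerVector::create(e->ah, e->n_max)),
    _["b_F"] = vec(e->db_F),
    _["H_F"] = mat(e->dH_F, IntegerVector::create(e->n_max, e->ah)),
    _["W_yR"] = mat(e->dW_yR, IntegerVector::create(e->ah, e->n_max)),
    _["b_R"] = vec(e->db_R),
    _["h_R"] = mat(e->dh_R, IntegerVector::create(1, e->ah)),
    _["W_attconv"] = convW(e->convA),
    _["b_attconv"] = convB(e->convA),
    _["W_fin"] = convW(e->convF),
    _["b_fin"] = convB(e->convF),
    _["W_out"] = mat(e->dW_out, IntegerVector::create(e->C, e->zdim)),
    _["b_o"] = vec(e->db_o));
  NumericMatrix pout(e->C, B);
  std::memcpy(pout.begin(), e->p.memptr(), sizeof(double) * e->C * B);
  return List::create(_["loss"] = loss, _["gradients"] = g, _["p"] = pout);
}

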