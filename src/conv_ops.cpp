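#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature tensors are R arrays with dim (H, W, C, N), column-major.
// Convolution kernels are R arrays with dim (kh, kw, Cin, Cout).
// All convolutions are stride 1 with zero "same" padding; kernels have
// odd extent so output spatial dims equal input dims.

static inline void dims4(const NumericVector &x, int d[4]) {
  IntegerVector dv = x.attr("dim");
  if (dv.size() != 4) stop("expected a 4-d tensor (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dv[i];
}

// im2col for one sample: rows index pixels (h + H*w), cols index
// (ki + kh*(kj + kw*ci)) matching the column-major kernel flattening.
static void im2col(const double *x, int H, int W, int Cin,
                   int kh, int kw, arma::mat &col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * ci);
        double *dst = col.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pw;
          if (sw < 0 || sw >= W) {
            std::fill(dst + (size_t)w * H, dst + (size_t)(w + 1) * H, 0.0);
            continue;
          }
          const double *src = xc + (size_t)sw * H;
          double *d = dst + (size_t)w * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - ph;
            d[h] = (sh < 0 || sh >= H) ? 0.0 : src[sh];
          }
        }
      }
    }
  }
}

// scatter-add of a column matrix back onto the input gradient
static void col2im_add(const arma::mat &col, int H, int W, int Cin,
                       int kh, int kw, double *dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    double *xc = dx + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * ci);
        const double *src = col.colptr(q);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pw;
          if (sw < 0 || sw >= W) continue;
          double *d = xc + (size_t)sw * H;
          const double *s = src + (size_t)w * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - ph;
            if (sh >= 0 && sh < H) d[sh] += s[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4]; dims4(x, dx);
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 4) stop("kernel must have dim (kh, kw, Cin, Cout)");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("kernel input channels do not match tensor");
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel extent must be odd");
  if (b.size() != Cout) stop("bias length must equal output channels");

  const int npix = H * W, kdim = kh * kw * Cin;
  arma::mat Wm(const_cast<double *>(w.begin()), kdim, Cout, false, true);
  arma::rowvec bv(const_cast<double *>(b.begin()), Cout, false, true);

  NumericVector y((size_t)npix * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col(npix, kdim);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * npix * Cin, H, W, Cin, kh, kw, col);
    arma::mat out(y.begin() + (size_t)n * npix * Cout, npix, Cout, false, true);
    out = col * Wm;
    out.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  int dxd[4]; dims4(x, dxd);
  int dyd[4]; dims4(dy, dyd);
  IntegerVector dw = w.attr("dim");
  const int H = dxd[0], W = dxd[1], Cin = dxd[2], N = dxd[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dyd[0] != H || dyd[1] != W || dyd[2] != Cout || dyd[3] != N)
    stop("gradient shape mismatch");

  const int npix = H * W, kdim = kh * kw * Cin;
  arma::mat Wm(const_cast<double *>(w.begin()), kdim, Cout, false, true);

  NumericVector dxv((size_t)npix * Cin * N);
  dxv.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dwv(w.size());
  dwv.attr("dim") = dw;
  NumericVector dbv(Cout);

  arma::mat dWm(dwv.begin(), kdim, Cout, false, true);
  arma::rowvec dbm(dbv.begin(), Cout, false, true);
  arma::mat col(npix, kdim);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * npix * Cin, H, W, Cin, kh, kw, col);
    arma::mat dYm(const_cast<double *>(dy.begin()) + (size_t)n * npix * Cout,
                  npix, Cout, false, true);
    dWm += col.t() * dYm;
    dbm += arma::sum(dYm, 0);
    arma::mat dcol = dYm * Wm.t();
    col2im_add(dcol, H, W, Cin, kh, kw, dxv.begin() + (size_t)n * npix * Cin);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling, stride 2; idx records the winning quadrant (0..3,
// first maximum wins) so the backward pass routes gradient uniquely.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double *pl = xp + (size_t)cn * H * W;
    double *po = yp + (size_t)cn * Ho * Wo;
    int *pi = ip + (size_t)cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h = 2 * ho, w = 2 * wo;
        double v[4] = {pl[h + H * w], pl[h + 1 + H * w],
                       pl[h + H * (w + 1)], pl[h + 1 + H * (w + 1)]};
        int best = 0;
        for (int q = 1; q < 4; ++q) if (v[q] > v[best]) best = q;
        po[ho + Ho * wo] = v[best];
        pi[ho + Ho * wo] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector idx, int H, int W) {
  int d[4]; dims4(dy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *dp = dy.begin();
  const int *ip = idx.begin();
  double *xp = dx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    double *pl = xp + (size_t)cn * H * W;
    const double *po = dp + (size_t)cn * Ho * Wo;
    const int *pi = ip + (size_t)cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int q = pi[ho + Ho * wo];
        const int h = 2 * ho + (q & 1), w = 2 * wo + (q >> 1);
        pl[h + H * w] += po[ho + Ho * wo];
      }
    }
  }
  return dx;
}

// Per-pixel means of the k smallest / k largest channel values.
// Ties are broken by channel index (stable), and the selected indices
// are returned so the backward pass distributes gradient consistently.
// [[Rcpp::export(name = ".osl_stats")]]
List osl_stats(NumericVector x, int k) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (k < 1 || k > C) stop("k must lie in [1, C]");
  const int npix = H * W;
  NumericVector small_((size_t)npix * N), large_((size_t)npix * N);
  small_.attr("dim") = IntegerVector::create(H, W, 1, N);
  large_.attr("dim") = IntegerVector::create(H, W, 1, N);
  IntegerVector si((size_t)npix * N * k), li((size_t)npix * N * k);
  si.attr("dim") = IntegerVector::create(npix, k, N);
  li.attr("dim") = IntegerVector::create(npix, k, N);

  std::vector<int> ord(C);
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n) {
    const double *base = xp + (size_t)n * npix * C;
    for (int p = 0; p < npix; ++p) {
      for (int c = 0; c < C; ++c) ord[c] = c;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        const double va = base[p + (size_t)a * npix];
        const double vb = base[p + (size_t)b * npix];
        return va < vb || (va == vb && a < b);
      });
      double s = 0.0, l = 0.0;
      for (int i = 0; i < k; ++i) {
        s += base[p + (size_t)ord[i] * npix];
        l += base[p + (size_t)ord[C - 1 - i] * npix];
        si[p + (size_t)i * npix + (size_t)n * npix * k] = ord[i];
        li[p + (size_t)i * npix + (size_t)n * npix * k] = ord[C - 1 - i];
      }
      small_[p + (size_t)n * npix] = s / k;
      large_[p + (size_t)n * npix] = l / k;
    }
  }
  return List::create(_["small"] = small_, _["large"] = large_,
                      _["small_idx"] = si, _["large_idx"] = li);
}

// [[Rcpp::export(name = ".osl_bw")]]
NumericVector osl_bw(NumericVector dsmall, NumericVector dlarge,
                     IntegerVector si, IntegerVector li, int C) {
  int d[4]; dims4(dsmall, d);
  const int H = d[0], W = d[1], N = d[3];
  IntegerVector sd = si.attr("dim");
  const int npix = H * W, k = sd[1];
  NumericVector dx((size_t)npix * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int p = 0; p < npix; ++p) {
      const double gs = dsmall[p + (size_t)n * npix] / k;
      const double gl = dlarge[p + (size_t)n * npix] / k;
      for (int i = 0; i < k; ++i) {
        const int cs = si[p + (size_t)i * npix + (size_t)n * npix * k];
        const int cl = li[p + (size_t)i * npix + (size_t)n * npix * k];
        dx[p + (size_t)cs * npix + (size_t)n * npix * C] += gs;
        dx[p + (size_t)cl * npix + (size_t)n * npix * C] += gl;
      }
    }
  }
  return dx;
}
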