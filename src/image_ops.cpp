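#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale morphology with a rectangular structuring element.
// Windows are clipped at the image border (the neighborhood is the
// intersection of the kh x kw rectangle with the image), which makes
// erosion/dilation exact inverses of each other on constant borders
// and matches the brute-force min/max definition.
static NumericMatrix minmax_rect(const NumericMatrix &img, int kh, int kw,
                                 bool take_max) {
  const int H = img.nrow(), W = img.ncol();
  const int rh = (kh - 1) / 2, rw = (kw - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // horizontal pass (across columns)
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) {
      const int w0 = std::max(0, w - rw), w1 = std::min(W - 1, w + rw);
      double v = img(h, w0);
      for (int ww = w0 + 1; ww <= w1; ++ww) {
        const double z = img(h, ww);
        v = take_max ? std::max(v, z) : std::min(v, z);
      }
      tmp(h, w) = v;
    }
  }
  // vertical pass (across rows)
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const int h0 = std::max(0, h - rh), h1 = std::min(H - 1, h + rh);
      double v = tmp(h0, w);
      for (int hh = h0 + 1; hh <= h1; ++hh) {
        const double z = tmp(hh, w);
        v = take_max ? std::max(v, z) : std::min(v, z);
      }
      out(h, w) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dilate_rect")]]
NumericMatrix dilate_rect(NumericMatrix img, int kh, int kw) {
  return minmax_rect(img, kh, kw, true);
}

// [[Rcpp::export(name = ".erode_rect")]]
NumericMatrix erode_rect(NumericMatrix img, int kh, int kw) {
  return minmax_rect(img, kh, kw, false);
}

// Fast-marching style inpainting: unknown pixels are ordered by their
// 4-connected BFS distance from the known region and filled layer by
// layer; each pixel becomes the inverse-square-distance weighted mean
// of already-known pixels within a Chebyshev radius. Deterministic and
// independent of traversal order within a layer.
// [[Rcpp::export(name = ".inpaint_fmm")]]
NumericVector inpaint_fmm(NumericVector img, IntegerMatrix mask, int radius) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = (d.size() > 2) ? d[2] : 1;
  if (mask.nrow() != H || mask.ncol() != W) stop("mask shape mismatch");
  if (radius < 1) stop("radius must be >= 1");

  std::vector<int> dist((size_t)H * W, -1);
  std::queue<int> q;
  int n_known = 0;
  for (int p = 0; p < H * W; ++p) {
    if (mask[p] == 0) { dist[p] = 0; q.push(p); ++n_known; }
  }
  if (n_known == 0) stop("mask covers the whole image; nothing to propagate from");

  // multi-source BFS distances
  while (!q.empty()) {
    const int p = q.front(); q.pop();
    const int h = p % H, w = p / H;
    const int nh[4] = {h - 1, h + 1, h, h};
    const int nw[4] = {w, w, w - 1, w + 1};
    for (int i = 0; i < 4; ++i) {
      if (nh[i] < 0 || nh[i] >= H || nw[i] < 0 || nw[i] >= W) continue;
      const int np = nh[i] + H * nw[i];
      if (dist[np] < 0) { dist[np] = dist[p] + 1; q.push(np); }
    }
  }

  NumericVector out = clone(img);
  int maxd = 0;
  for (int p = 0; p < H * W; ++p) maxd = std::max(maxd, dist[p]);
  std::vector<char> known((size_t)H * W);
  for (int p = 0; p < H * W; ++p) known[p] = (dist[p] == 0);

  for (int layer = 1; layer <= maxd; ++layer) {
    std::vector<int> todo;
    for (int p = 0; p < H * W; ++p) if (dist[p] == layer) todo.push_back(p);
    for (int t : todo) {
      const int h = t % H, w = t / H;
      for (int c = 0; c < C; ++c) {
        double acc = 0.0, wsum = 0.0;
        for (int dw = -radius; dw <= radius; ++dw) {
          const int ww = w + dw;
          if (ww < 0 || ww >= W) continue;
          for (int dh = -radius; dh <= radius; ++dh) {
            const int hh = h + dh;
            if (hh < 0 || hh >= H) continue;
            const int p = hh + H * ww;
            if (!known[p]) continue;
            const double d2 = (double)dh * dh + (double)dw * dw;
            const double wt = 1.0 / (d2 + 1e-9);
            acc += wt * out[p + (size_t)c * H * W];
            wsum += wt;
          }
        }
        if (wsum > 0) out[t + (size_t)c * H * W] = acc / wsum;
        // a layer-(d) pixel always has a layer-(d-1) 4-neighbor, so
        // wsum > 0 is guaranteed for radius >= 1
      }
    }
    for (int t : todo) known[t] = 1;
  }
  return out;
}

// Affine warp by inverse mapping: for each output pixel (r, c) the
// source location is (m[0]*r + m[1]*c + m[2], m[3]*r + m[4]*c + m[5])
// in 0-based (row, col) coordinates. bilinear = FALSE gives nearest
// neighbor. border: 0 = constant fill, 1 = symmetric reflection.
// [[Rcpp::export(name = ".affine_warp")]]
NumericVector affine_warp(NumericVector img, NumericVector m,
                          bool bilinear, int border, double fill) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = (d.size() > 2) ? d[2] : 1;
  if (m.size() != 6) stop("affine map must have 6 coefficients");
  NumericVector out(img.size());
  out.attr("dim") = d;

  auto reflect = [](double x, int n) {
    // symmetric reflection: ... 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
    if (n == 1) return 0.0;
    const double period = 2.0 * n;
    x -= std::floor(x / period) * period;   // x mod period, in [0, period)
    if (x >= n) x = period - 1.0 - x;
    if (x < 0) x = 0.0;
    return x;
  };

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double sr = m[0] * r + m[1] * c + m[2];
      const double sc = m[3] * r + m[4] * c + m[5];
      for (int ch = 0; ch < C; ++ch) {
        const double *pl = img.begin() + (size_t)ch * H * W;
        double val;
        if (!bilinear) {
          double rr = std::floor(sr + 0.5), cc = std::floor(sc + 0.5);
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) {
            if (border == 1) { rr = reflect(rr, H); cc = reflect(cc, W); }
            else { out[r + H * c + (size_t)ch * H * W] = fill; continue; }
          }
          val = pl[(int)rr + H * (int)cc];
        } else {
          double rr = sr, cc = sc;
          bool outside = (rr < 0 || rr > H - 1 || cc < 0 || cc > W - 1);
          if (outside && border == 0) {
            out[r + H * c + (size_t)ch * H * W] = fill;
            continue;
          }
          const int r0f = (int)std::floor(rr), c0f = (int)std::floor(cc);
          const double fr = rr - r0f, fc = cc - c0f;
          auto sample = [&](int ri, int ci) {
            double rd = ri, cd = ci;
            if (rd < 0 || rd >= H || cd < 0 || cd >= W) {
              if (border == 1) { rd = reflect(rd, H); cd = reflect(cd, W); }
              else return fill;
            }
            return pl[(int)rd + H * (int)cd];
          };
          val = (1 - fr) * (1 - fc) * sample(r0f, c0f) +
                fr * (1 - fc) * sample(r0f + 1, c0f) +
                (1 - fr) * fc * sample(r0f, c0f + 1) +
                fr * fc * sample(r0f + 1, c0f + 1);
        }
        out[r + H * c + (size_t)ch * H * W] = val;
      }
    }
  }
  return out;
}

// Minimum distance from each pixel to a sampled curve, computed only
// within `radius` of the samples (Inf elsewhere). Used to rasterize
// hair strands with a width profile.
// [[Rcpp::export(name = ".curve_distance")]]
NumericMatrix curve_distance(int H, int W, NumericVector rs, NumericVector cs,
                             double radius) {
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), R_PosInf);
  const int n = rs.size();
  const int rad = (int)std::ceil(radius);
  for (int i = 0; i < n; ++i) {
    const double pr = rs[i], pc = cs[i];
    const int h0 = std::max(0, (int)std::floor(pr - rad));
    const int h1 = std::min(H - 1, (int)std::ceil(pr + rad));
    const int w0 = std::max(0, (int)std::floor(pc - rad));
    const int w1 = std::min(W - 1, (int)std::ceil(pc + rad));
    for (int w = w0; w <= w1; ++w) {
      for (int h = h0; h <= h1; ++h) {
        const double dr = h - pr, dc = w - pc;
        const double dd = std::sqrt(dr * dr + dc * dc);
        if (dd < out(h, w)) out(h, w) = dd;
      }
    }
  }
  return out;
}
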