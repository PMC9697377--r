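// Compiled kernels for the detection network.
//
// Array layout conventions (all R arrays, column-major):
//   feature maps  : dim = c(H, W, C)              -- rows, cols, channels
//   conv weights  : dim = c(kh, kw, Cin, Cout)
//   offset fields : dim = c(Ho, Wo, 2*K)          -- per tap t (1-based, R array
//                   order over (kh, kw)): channel 2t-1 = row offset, 2t = col
//                   offset, in feature-map pixels
// Spatial coordinates are zero-based continuous; integer grid points are pixel
// centres. Sampling outside the grid contributes zero (the tent kernel's
// max(0, 1-|.|) support enforces this).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int conv_out(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = conv_out(H, kh, stride, pad, dil);
  int Wo = conv_out(W, kw, stride, pad, dil);
  NumericVector y(Ho * Wo * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  bool hasb = bias.size() > 0;
  for (int co = 0; co < Cout; ++co) {
    double b = hasb ? bias[co] : 0.0;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = b;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            int c = wo * stride - pad + kj * dil;
            if (c < 0 || c >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int r = ho * stride - pad + ki * dil;
              if (r < 0 || r >= H) continue;
              acc += w[ki + kh * (kj + kw * (ci + (size_t)Cin * co))] *
                     x[r + H * (c + (size_t)W * ci)];
            }
          }
        }
        y[ho + Ho * (wo + (size_t)Wo * co)] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double g = gy[ho + Ho * (wo + (size_t)Wo * co)];
        if (g == 0.0) continue;
        gb[co] += g;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            int c = wo * stride - pad + kj * dil;
            if (c < 0 || c >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int r = ho * stride - pad + ki * dil;
              if (r < 0 || r >= H) continue;
              size_t wi = ki + kh * (kj + kw * (ci + (size_t)Cin * co));
              size_t xi = r + H * (c + (size_t)W * ci);
              gw[wi] += g * x[xi];
              gx[xi] += g * w[wi];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear read of channel ch at continuous (r, c); zero outside the grid.
static inline double bsamp(const double* x, int H, int W, int ch,
                           double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double out = 0.0;
  for (int dc = 0; dc <= 1; ++dc) {
    int cc = c0 + dc;
    if (cc < 0 || cc >= W) continue;
    double wc = 1.0 - std::fabs(c - cc);
    if (wc <= 0.0) continue;
    for (int dr = 0; dr <= 1; ++dr) {
      int rr = r0 + dr;
      if (rr < 0 || rr >= H) continue;
      double wr = 1.0 - std::fabs(r - rr);
      if (wr <= 0.0) continue;
      out += wr * wc * x[rr + H * (cc + (size_t)W * ch)];
    }
  }
  return out;
}

// Scatter gradient g through the bilinear read; also return d/d(r), d/d(c).
static inline void bsamp_bwd(const double* x, double* gx, int H, int W, int ch,
                             double r, double c, double g,
                             double* dr_out, double* dc_out) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double dr_acc = 0.0, dc_acc = 0.0;
  for (int dc = 0; dc <= 1; ++dc) {
    int cc = c0 + dc;
    if (cc < 0 || cc >= W) continue;
    double wc = 1.0 - std::fabs(c - cc);
    double dwc = (cc >= c) ? 1.0 : -1.0;  // d wc / d c
    if (wc < 0.0) continue;
    for (int dr = 0; dr <= 1; ++dr) {
      int rr = r0 + dr;
      if (rr < 0 || rr >= H) continue;
      double wr = 1.0 - std::fabs(r - rr);
      double dwr = (rr >= r) ? 1.0 : -1.0;
      if (wr < 0.0) continue;
      size_t xi = rr + H * (cc + (size_t)W * ch);
      double xv = x[xi];
      if (gx) gx[xi] += g * wr * wc;
      dr_acc += g * dwr * wc * xv;
      dc_acc += g * wr * dwc * xv;
    }
  }
  if (dr_out) *dr_out += dr_acc;
  if (dc_out) *dc_out += dc_acc;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericVector x, NumericVector r,
                                  NumericVector c, IntegerVector ch) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1];
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = bsamp(REAL(x), H, W, ch[i] - 1, r[i], c[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_deform_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, NumericVector off,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = off.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = od[0], Wo = od[1];
  int K = kh * kw;
  NumericVector y(Ho * Wo * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  bool hasb = bias.size() > 0;
  const double* xp = REAL(x);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int t = 0; t < K; ++t) {
        int ki = t % kh, kj = t / kh;
        double r = ho * stride - pad + ki * dil +
                   off[ho + Ho * (wo + (size_t)Wo * (2 * t))];
        double c = wo * stride - pad + kj * dil +
                   off[ho + Ho * (wo + (size_t)Wo * (2 * t + 1))];
        for (int ci = 0; ci < Cin; ++ci) {
          double xv = bsamp(xp, H, W, ci, r, c);
          if (xv == 0.0) continue;
          for (int co = 0; co < Cout; ++co)
            y[ho + Ho * (wo + (size_t)Wo * co)] +=
                w[ki + kh * (kj + kw * (ci + (size_t)Cin * co))] * xv;
        }
      }
      if (hasb)
        for (int co = 0; co < Cout; ++co)
          y[ho + Ho * (wo + (size_t)Wo * co)] += bias[co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_deform_bwd(NumericVector x, NumericVector w, NumericVector off,
                    NumericVector gy, int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = off.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = od[0], Wo = od[1];
  int K = kh * kw;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout), goff(off.size());
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  goff.attr("dim") = od;
  const double* xp = REAL(x);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int co = 0; co < Cout; ++co)
        gb[co] += gy[ho + Ho * (wo + (size_t)Wo * co)];
      for (int t = 0; t < K; ++t) {
        int ki = t % kh, kj = t / kh;
        size_t oir = ho + Ho * (wo + (size_t)Wo * (2 * t));
        size_t oic = ho + Ho * (wo + (size_t)Wo * (2 * t + 1));
        double r = ho * stride - pad + ki * dil + off[oir];
        double c = wo * stride - pad + kj * dil + off[oic];
        for (int ci = 0; ci < Cin; ++ci) {
          // dL/d(sample) accumulated over output channels
          double gs = 0.0;
          size_t wbase = ki + kh * (kj + (size_t)kw * ci);
          for (int co = 0; co < Cout; ++co)
            gs += gy[ho + Ho * (wo + (size_t)Wo * co)] *
                  w[wbase + (size_t)kh * kw * Cin * co];
          double xv = bsamp(xp, H, W, ci, r, c);
          for (int co = 0; co < Cout; ++co)
            gw[wbase + (size_t)kh * kw * Cin * co] +=
                gy[ho + Ho * (wo + (size_t)Wo * co)] * xv;
          if (gs != 0.0)
            bsamp_bwd(xp, REAL(gx), H, W, ci, r, c, gs,
                      &goff[oir], &goff[oic]);
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb,
                      _["goff"] = goff);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  NumericVector y((size_t)4 * x.size());
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int wcol = 0; wcol < W; ++wcol)
      for (int h = 0; h < H; ++h) {
        double v = x[h + H * (wcol + (size_t)W * c)];
        size_t base = 2 * h + 2 * H * (2 * wcol + (size_t)2 * W * c);
        y[base] = v;
        y[base + 1] = v;
        y[base + 2 * H] = v;
        y[base + 2 * H + 1] = v;
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  int H = yd[0] / 2, W = yd[1] / 2, C = yd[2];
  NumericVector gx((size_t)H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int wcol = 0; wcol < W; ++wcol)
      for (int h = 0; h < H; ++h) {
        size_t base = 2 * h + 2 * H * (2 * wcol + (size_t)2 * W * c);
        gx[h + H * (wcol + (size_t)W * c)] =
            gy[base] + gy[base + 1] + gy[base + 2 * H] + gy[base + 2 * H + 1];
      }
  return gx;
}

// 2x2 max pooling, stride 2 (odd trailing row/col dropped); idx is 0-based
// linear index into x of each chosen element, for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int bi = -1;
        for (int dc = 0; dc <= 1; ++dc)
          for (int dr = 0; dr <= 1; ++dr) {
            int r = 2 * ho + dr, cc = 2 * wo + dc;
            size_t xi = r + H * (cc + (size_t)W * c);
            if (x[xi] > best) { best = x[xi]; bi = (int)xi; }
          }
        size_t yi = ho + Ho * (wo + (size_t)Wo * c);
        y[yi] = best;
        idx[yi] = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2]);
  gx.attr("dim") = xdim;
  for (int i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// ROI align over one feature map. rois: n x 4 matrix (r1, c1, r2, c2) in
// feature-map coordinates (continuous, half-open). Output (ph, pw, C, n).
// Each output bin averages nsamp x nsamp bilinear samples.
// [[Rcpp::export]]
NumericVector cpp_roialign_fwd(NumericVector feat, NumericMatrix rois,
                               int ph, int pw, int nsamp) {
  IntegerVector fd = feat.attr("dim");
  int H = fd[0], W = fd[1], C = fd[2];
  int n = rois.nrow();
  NumericVector y((size_t)ph * pw * C * n);
  y.attr("dim") = IntegerVector::create(ph, pw, C, n);
  const double* fp = REAL(feat);
  double inv = 1.0 / (nsamp * nsamp);
  for (int i = 0; i < n; ++i) {
    double r1 = rois(i, 0), c1 = rois(i, 1), r2 = rois(i, 2), c2 = rois(i, 3);
    double bh = (r2 - r1) / ph, bw = (c2 - c1) / pw;
    for (int c = 0; c < C; ++c)
      for (int pj = 0; pj < pw; ++pj)
        for (int pi = 0; pi < ph; ++pi) {
          double acc = 0.0;
          for (int sj = 0; sj < nsamp; ++sj)
            for (int si = 0; si < nsamp; ++si) {
              double rr = r1 + (pi + (si + 0.5) / nsamp) * bh - 0.5;
              double cc = c1 + (pj + (sj + 0.5) / nsamp) * bw - 0.5;
              acc += bsamp(fp, H, W, c, rr, cc);
            }
          y[pi + ph * (pj + pw * (c + (size_t)C * i))] = acc * inv;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_roialign_bwd(NumericVector gy, NumericMatrix rois,
                               IntegerVector fdim, int ph, int pw, int nsamp) {
  int H = fdim[0], W = fdim[1], C = fdim[2];
  int n = rois.nrow();
  NumericVector gx((size_t)H * W * C);
  gx.attr("dim") = fdim;
  double inv = 1.0 / (nsamp * nsamp);
  // bsamp_bwd needs an x pointer only for offset grads; pass gx as dummy x
  // with null offset outputs (x values unused when dr/dc outputs are null...
  // they are used, so use a zero buffer instead).
  std::vector<double> zero((size_t)H * W * C, 0.0);
  for (int i = 0; i < n; ++i) {
    double r1 = rois(i, 0), c1 = rois(i, 1), r2 = rois(i, 2), c2 = rois(i, 3);
    double bh = (r2 - r1) / ph, bw = (c2 - c1) / pw;
    for (int c = 0; c < C; ++c)
      for (int pj = 0; pj < pw; ++pj)
        for (int pi = 0; pi < ph; ++pi) {
          double g = gy[pi + ph * (pj + pw * (c + (size_t)C * i))] * inv;
          if (g == 0.0) continue;
          for (int sj = 0; sj < nsamp; ++sj)
            for (int si = 0; si < nsamp; ++si) {
              double rr = r1 + (pi + (si + 0.5) / nsamp) * bh - 0.5;
              double cc = c1 + (pj + (sj + 0.5) / nsamp) * bw - 0.5;
              bsamp_bwd(zero.data(), REAL(gx), H, W, c, rr, cc, g,
                        nullptr, nullptr);
            }
        }
  }
  return gx;
}

// Greedy non-maximum suppression. boxes: n x 4 (x1, y1, x2, y2); scores
// descending is NOT assumed -- order computed here. Returns 1-based keep
// indices in descending-score order (ties keep input order).
// [[Rcpp::export]]
IntegerVector cpp_nms(NumericMatrix boxes, NumericVector scores,
                      double iou_thresh) {
  int n = boxes.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return scores[a] > scores[b]; });
  std::vector<bool> dead(n, false);
  std::vector<int> keep;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    if (dead[i]) continue;
    keep.push_back(i + 1);
    double ax1 = boxes(i, 0), ay1 = boxes(i, 1), ax2 = boxes(i, 2),
           ay2 = boxes(i, 3);
    double aarea = std::max(0.0, ax2 - ax1) * std::max(0.0, ay2 - ay1);
    for (int oj = oi + 1; oj < n; ++oj) {
      int j = ord[oj];
      if (dead[j]) continue;
      double ix1 = std::max(ax1, boxes(j, 0)), iy1 = std::max(ay1, boxes(j, 1));
      double ix2 = std::min(ax2, boxes(j, 2)), iy2 = std::min(ay2, boxes(j, 3));
      double inter = std::max(0.0, ix2 - ix1) * std::max(0.0, iy2 - iy1);
      double barea = std::max(0.0, boxes(j, 2) - boxes(j, 0)) *
                     std::max(0.0, boxes(j, 3) - boxes(j, 1));
      double uni = aarea + barea - inter;
      if (uni > 0 && inter / uni > iou_thresh) dead[j] = true;
    }
  }
  return IntegerVector(keep.begin(), keep.end());
}
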