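#include <Rcpp.h>
using namespace Rcpp;

// Feature batches are R arrays of dim (N, C, H, W), column-major, so element
// (n, c, h, w) sits at n + N*(c + C*(h + H*w)) (all 0-based here).
// Kernels are arrays of dim (Cout, Cin, KH, KW).

static inline int out_extent(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad,
                             int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Co = wd[0], Ci = wd[1], KH = wd[2], KW = wd[3];
  if (Ci != C) stop("conv2d: input has %d channels, kernel expects %d", C, Ci);
  const int Ho = out_extent(H, KH, stride, pad, dil);
  const int Wo = out_extent(W, KW, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: output extent would be empty");
  const bool has_bias = bias.size() > 0;

  NumericVector y(N * Co * Ho * Wo);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();

  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int co = 0; co < Co; ++co) {
        double *yk = py + N * (co + Co * (ho + Ho * wo));
        if (has_bias)
          for (int n = 0; n < N; ++n) yk[n] = bias[co];
        for (int kw = 0; kw < KW; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            for (int ci = 0; ci < C; ++ci) {
              const double wv = pw[co + Co * (ci + Ci * (kh + KH * kw))];
              if (wv == 0.0) continue;
              const double *xk = px + N * (ci + C * (hi + H * wi));
              for (int n = 0; n < N; ++n) yk[n] += wv * xk[n];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(N, Co, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int dil, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Co = wd[0], Ci = wd[1], KH = wd[2], KW = wd[3];
  const int Ho = out_extent(H, KH, stride, pad, dil);
  const int Wo = out_extent(W, KW, stride, pad, dil);

  NumericVector dx(N * C * H * W), dw(Co * Ci * KH * KW), db(has_bias ? Co : 0);
  const double *px = x.begin(), *pw = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();

  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int co = 0; co < Co; ++co) {
        const double *dyk = pdy + N * (co + Co * (ho + Ho * wo));
        if (has_bias) {
          double s = 0.0;
          for (int n = 0; n < N; ++n) s += dyk[n];
          db[co] += s;
        }
        for (int kw = 0; kw < KW; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            for (int ci = 0; ci < C; ++ci) {
              const double wv = pw[co + Co * (ci + Ci * (kh + KH * kw))];
              const double *xk = px + N * (ci + C * (hi + H * wi));
              double *dxk = pdx + N * (ci + C * (hi + H * wi));
              double acc = 0.0;
              for (int n = 0; n < N; ++n) {
                acc += dyk[n] * xk[n];
                dxk[n] += dyk[n] * wv;
              }
              pdw[co + Co * (ci + Ci * (kh + KH * kw))] += acc;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(N, C, H, W);
  dw.attr("dim") = IntegerVector::create(Co, Ci, KH, KW);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear resize of a (N, C, H, W) batch to (N, C, Ho, Wo) with
// half-pixel-centre sampling and edge clamping.
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y(N * C * Ho * Wo);
  const double *px = x.begin();
  double *py = y.begin();
  const double sh = (double)H / Ho, sw = (double)W / Wo;

  for (int wo = 0; wo < Wo; ++wo) {
    double wsrc = (wo + 0.5) * sw - 0.5;
    int w0 = (int)std::floor(wsrc);
    double fw = wsrc - w0;
    int w1 = w0 + 1;
    if (w0 < 0) w0 = 0;
    if (w1 < 0) w1 = 0;
    if (w0 > W - 1) w0 = W - 1;
    if (w1 > W - 1) w1 = W - 1;
    for (int ho = 0; ho < Ho; ++ho) {
      double hsrc = (ho + 0.5) * sh - 0.5;
      int h0 = (int)std::floor(hsrc);
      double fh = hsrc - h0;
      int h1 = h0 + 1;
      if (h0 < 0) h0 = 0;
      if (h1 < 0) h1 = 0;
      if (h0 > H - 1) h0 = H - 1;
      if (h1 > H - 1) h1 = H - 1;
      for (int c = 0; c < C; ++c) {
        const double *p00 = px + N * (c + C * (h0 + H * w0));
        const double *p10 = px + N * (c + C * (h1 + H * w0));
        const double *p01 = px + N * (c + C * (h0 + H * w1));
        const double *p11 = px + N * (c + C * (h1 + H * w1));
        double *yk = py + N * (c + C * (ho + Ho * wo));
        for (int n = 0; n < N; ++n) {
          double top = p00[n] * (1 - fh) + p10[n] * fh;
          double bot = p01[n] * (1 - fh) + p11[n] * fh;
          yk[n] = top * (1 - fw) + bot * fw;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  return y;
}
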