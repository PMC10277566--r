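// Low-level conv/pool kernels for the EEG backbones.
// Tensor layout everywhere: R array with dim (N, C, H, W), column-major,
// so element (n,c,h,w) sits at n + N*(c + C*(h + H*w)).
// Convolutions are stride-1 with zero padding; pooling carries its own
// stride. Each sample is staged into a contiguous (w fastest) buffer before
// im2col/col2im so the inner loops run at unit stride.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t idx4(int n, int c, int h, int w,
                            int N, int C, int H) {
  return (R_xlen_t)n +
         (R_xlen_t)N * ((R_xlen_t)c +
         (R_xlen_t)C * ((R_xlen_t)h + (R_xlen_t)H * (R_xlen_t)w));
}

// stage sample n, channel group g into xb[w + W*(h + H*ci)], ci local
static void load_sample(const double* x, std::vector<double>& xb,
                        int n, int g, int N, int C, int H, int W, int Cin_g) {
  for (int ci = 0; ci < Cin_g; ++ci)
    for (int h = 0; h < H; ++h) {
      double* dst = xb.data() + (R_xlen_t)W * (h + (R_xlen_t)H * ci);
      const double* src = x + idx4(n, g * Cin_g + ci, h, 0, N, C, H);
      R_xlen_t stride = (R_xlen_t)N * C * H;
      for (int w = 0; w < W; ++w) dst[w] = src[(R_xlen_t)w * stride];
    }
}

// cols(r, ho + Hout*wo) with r = ci + Cin_g*(i + kh*j), from the staged buffer
static void im2col_buf(const std::vector<double>& xb, arma::mat& cols,
                       int H, int W, int Cin_g, int kh, int kw,
                       int pad_h, int pad_w, int Hout, int Wout) {
  int K = Cin_g * kh * kw;
  for (int j = 0; j < kw; ++j)
    for (int i = 0; i < kh; ++i)
      for (int ci = 0; ci < Cin_g; ++ci) {
        int r = ci + Cin_g * (i + kh * j);
        for (int ho = 0; ho < Hout; ++ho) {
          int hin = ho - pad_h + i;
          double* dst = cols.memptr() + r + (R_xlen_t)K * ho;
          R_xlen_t dstride = (R_xlen_t)K * Hout;
          if (hin < 0 || hin >= H) {
            for (int wo = 0; wo < Wout; ++wo) dst[(R_xlen_t)wo * dstride] = 0.0;
            continue;
          }
          const double* src = xb.data() + (R_xlen_t)W * (hin + (R_xlen_t)H * ci);
          for (int wo = 0; wo < Wout; ++wo) {
            int win = wo - pad_w + j;
            dst[(R_xlen_t)wo * dstride] =
                (win >= 0 && win < W) ? src[win] : 0.0;
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int pad_h, int pad_w, int groups) {
  IntegerVector xd = x.attr("dim");  // N, C, H, W
  IntegerVector wd = w.attr("dim");  // Cout, Cin_g, kh, kw
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cin_g = wd[1], kh = wd[2], kw = wd[3];
  if (C != Cin_g * groups) stop("conv2d: channel/group mismatch");
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  int Cout_g = Cout / groups;
  int Hout = H + 2 * pad_h - kh + 1;
  int Wout = W + 2 * pad_w - kw + 1;
  if (Hout < 1 || Wout < 1)
    stop("conv2d: input %d x %d collapses under kernel %d x %d", H, W, kh, kw);
  bool has_b = (b.size() == Cout);

  NumericVector y((R_xlen_t)N * Cout * Hout * Wout);
  y.attr("dim") = IntegerVector::create(N, Cout, Hout, Wout);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  int K = Cin_g * kh * kw;
  arma::mat cols(K, (R_xlen_t)Hout * Wout);
  arma::mat Wm(Cout_g, K);
  std::vector<double> xb((R_xlen_t)Cin_g * H * W);

  for (int g = 0; g < groups; ++g) {
    for (int o = 0; o < Cout_g; ++o)
      for (int q = 0; q < K; ++q)
        Wm(o, q) = wp[(R_xlen_t)(g * Cout_g + o) + (R_xlen_t)Cout * q];
    for (int n = 0; n < N; ++n) {
      load_sample(xp, xb, n, g, N, C, H, W, Cin_g);
      im2col_buf(xb, cols, H, W, Cin_g, kh, kw, pad_h, pad_w, Hout, Wout);
      arma::mat Y = Wm * cols;  // Cout_g x (Hout*Wout)
      for (int o = 0; o < Cout_g; ++o) {
        double bias = has_b ? b[g * Cout_g + o] : 0.0;
        const double* Yp = Y.memptr() + o;
        R_xlen_t stride = (R_xlen_t)N * Cout * Hout;  // w stride in y
        double* base = yp + idx4(n, g * Cout_g + o, 0, 0, N, Cout, Hout);
        for (int wo = 0; wo < Wout; ++wo)
          for (int ho = 0; ho < Hout; ++ho)
            base[(R_xlen_t)ho * (R_xlen_t)N * Cout + (R_xlen_t)wo * stride] =
                Yp[(R_xlen_t)Cout_g * (ho + (R_xlen_t)Hout * wo)] + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int pad_h, int pad_w, int groups, bool need_gx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cin_g = wd[1], kh = wd[2], kw = wd[3];
  int Hout = yd[2], Wout = yd[3];
  int Cout_g = Cout / groups;
  int K = Cin_g * kh * kw;

  NumericVector gw((R_xlen_t)w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  NumericVector gx(need_gx ? (R_xlen_t)x.size() : (R_xlen_t)0);
  if (need_gx) gx.attr("dim") = xd;
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gyp = REAL(gy);
  double* gxp = need_gx ? REAL(gx) : nullptr;

  arma::mat cols(K, (R_xlen_t)Hout * Wout);
  arma::mat Wm(Cout_g, K);
  arma::mat Gy(Cout_g, (R_xlen_t)Hout * Wout);
  std::vector<double> xb((R_xlen_t)Cin_g * H * W);
  std::vector<double> gxb((R_xlen_t)Cin_g * H * W);

  for (int g = 0; g < groups; ++g) {
    arma::mat gWm(Cout_g, K, arma::fill::zeros);
    for (int o = 0; o < Cout_g; ++o)
      for (int q = 0; q < K; ++q)
        Wm(o, q) = wp[(R_xlen_t)(g * Cout_g + o) + (R_xlen_t)Cout * q];
    for (int n = 0; n < N; ++n) {
      for (int o = 0; o < Cout_g; ++o) {
        const double* base = gyp + idx4(n, g * Cout_g + o, 0, 0, N, Cout, Hout);
        for (int wo = 0; wo < Wout; ++wo)
          for (int ho = 0; ho < Hout; ++ho)
            Gy(o, ho + (R_xlen_t)Hout * wo) =
                base[(R_xlen_t)ho * (R_xlen_t)N * Cout +
                     (R_xlen_t)wo * (R_xlen_t)N * Cout * Hout];
        gb[g * Cout_g + o] += arma::accu(Gy.row(o));
      }
      load_sample(xp, xb, n, g, N, C, H, W, Cin_g);
      im2col_buf(xb, cols, H, W, Cin_g, kh, kw, pad_h, pad_w, Hout, Wout);
      gWm += Gy * cols.t();
      if (need_gx) {
        arma::mat Gcols = Wm.t() * Gy;  // K x (Hout*Wout), col2im follows
        std::fill(gxb.begin(), gxb.end(), 0.0);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i)
            for (int ci = 0; ci < Cin_g; ++ci) {
              int r = ci + Cin_g * (i + kh * j);
              for (int ho = 0; ho < Hout; ++ho) {
                int hin = ho - pad_h + i;
                if (hin < 0 || hin >= H) continue;
                double* dst = gxb.data() + (R_xlen_t)W * (hin + (R_xlen_t)H * ci);
                const double* src = Gcols.memptr() + r + (R_xlen_t)K * ho;
                for (int wo = 0; wo < Wout; ++wo) {
                  int win = wo - pad_w + j;
                  if (win >= 0 && win < W)
                    dst[win] += src[(R_xlen_t)K * Hout * wo];
                }
              }
            }
        // scatter the contiguous buffer back to (N,C,H,W)
        for (int ci = 0; ci < Cin_g; ++ci)
          for (int h = 0; h < H; ++h) {
            const double* src = gxb.data() + (R_xlen_t)W * (h + (R_xlen_t)H * ci);
            double* dst = gxp + idx4(n, g * Cin_g + ci, h, 0, N, C, H);
            R_xlen_t stride = (R_xlen_t)N * C * H;
            for (int wcol = 0; wcol < W; ++wcol)
              dst[(R_xlen_t)wcol * stride] += src[wcol];
          }
      }
    }
    for (int o = 0; o < Cout_g; ++o)
      for (int q = 0; q < K; ++q)
        gw[(R_xlen_t)(g * Cout_g + o) + (R_xlen_t)Cout * q] = gWm(o, q);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List pool2d_fwd(NumericVector x, int kh, int kw, int sh, int sw, bool max_pool) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Hout = (H - kh) / sh + 1;
  int Wout = (W - kw) / sw + 1;
  if (Hout < 1 || Wout < 1)
    stop("pool2d: input %d x %d collapses under window %d x %d", H, W, kh, kw);

  NumericVector y((R_xlen_t)N * C * Hout * Wout);
  y.attr("dim") = IntegerVector::create(N, C, Hout, Wout);
  IntegerVector amax(max_pool ? y.size() : (R_xlen_t)0);
  const double* xp = REAL(x);
  double* yp = REAL(y);

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          R_xlen_t oi = idx4(n, c, ho, wo, N, C, Hout);
          if (max_pool) {
            double best = -std::numeric_limits<double>::infinity();
            R_xlen_t besti = 0;
            for (int j = 0; j < kw; ++j)
              for (int i = 0; i < kh; ++i) {
                R_xlen_t ii = idx4(n, c, ho * sh + i, wo * sw + j, N, C, H);
                if (xp[ii] > best) { best = xp[ii]; besti = ii; }
              }
            yp[oi] = best;
            amax[oi] = (int)besti;
          } else {
            double s = 0.0;
            for (int j = 0; j < kw; ++j)
              for (int i = 0; i < kh; ++i)
                s += xp[idx4(n, c, ho * sh + i, wo * sw + j, N, C, H)];
            yp[oi] = s / (kh * kw);
          }
        }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector pool2d_bwd(NumericVector gy, IntegerVector xdim,
                         int kh, int kw, int sh, int sw,
                         bool max_pool, IntegerVector amax) {
  int N = xdim[0], C = xdim[1], H = xdim[2];
  IntegerVector yd = gy.attr("dim");
  int Hout = yd[2], Wout = yd[3];

  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  double inv = 1.0 / (kh * kw);

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          R_xlen_t oi = idx4(n, c, ho, wo, N, C, Hout);
          if (max_pool) {
            gxp[(R_xlen_t)amax[oi]] += gyp[oi];
          } else {
            double g = gyp[oi] * inv;
            for (int j = 0; j < kw; ++j)
              for (int i = 0; i < kh; ++i)
                gxp[idx4(n, c, ho * sh + i, wo * sw + j, N, C, H)] += g;
          }
        }
  return gx;
}
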