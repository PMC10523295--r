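#include <Rcpp.h>
using namespace Rcpp;

// Tensors are column-major R arrays.
// Activations: [H, W, C, N]; kernels: [kh, kw, Cin, Cout].
// Convolution is expressed as im2col + BLAS matmul on the R side; the
// compiled part is the patch gather/scatter.

static inline int idx4(int a, int b, int c, int d, int A, int B, int C) {
  return a + A * (b + B * (c + C * d));
}

// Patch matrix [Ho*Wo*N, kh*kw*Cin]; row r = ho + Ho*(wo + Wo*n),
// column k = i + kh*(j + kw*ci). Out-of-image taps are zero (padding).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector xd,
                         int kh, int kw, int stride, int pad) {
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int R = Ho * Wo * N;
  NumericMatrix out(R, kh * kw * Cin);
  for (int ci = 0; ci < Cin; ++ci)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * ci);
        double *col = &out(0, k);
        for (int n = 0; n < N; ++n)
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + j;
            const int r0 = Ho * (wo + Wo * n);
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              col[ho + r0] = x[idx4(hi, wi, ci, n, H, W, Cin)];
            }
          }
      }
  return out;
}

// Scatter-add transpose of im2col: cols [Ho*Wo*N, kh*kw*Cin] -> [H,W,Cin,N].
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, IntegerVector xd,
                         int kh, int kw, int stride, int pad) {
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * Cin * N);
  for (int ci = 0; ci < Cin; ++ci)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * ci);
        const double *col = &cols(0, k);
        for (int n = 0; n < N; ++n)
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + j;
            const int r0 = Ho * (wo + Wo * n);
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              gx[idx4(hi, wi, ci, n, H, W, Cin)] += col[ho + r0];
            }
          }
      }
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  return gx;
}

// 2x2 average pooling, stride 2; trailing odd row/column dropped.
// [[Rcpp::export]]
NumericVector avgpool2_fw_cpp(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int h = 2 * ho, w = 2 * wo;
          double s = x[idx4(h, w, c, n, H, W, C)] +
                     x[idx4(h + 1, w, c, n, H, W, C)] +
                     x[idx4(h, w + 1, c, n, H, W, C)] +
                     x[idx4(h + 1, w + 1, c, n, H, W, C)];
          y[idx4(ho, wo, c, n, Ho, Wo, C)] = 0.25 * s;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bw_cpp(NumericVector gy, IntegerVector yd,
                              IntegerVector xd) {
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = xd[0], W = xd[1];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = 0.25 * gy[idx4(ho, wo, c, n, Ho, Wo, C)];
          const int h = 2 * ho, w = 2 * wo;
          gx[idx4(h, w, c, n, H, W, C)] += g;
          gx[idx4(h + 1, w, c, n, H, W, C)] += g;
          gx[idx4(h, w + 1, c, n, H, W, C)] += g;
          gx[idx4(h + 1, w + 1, c, n, H, W, C)] += g;
        }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}
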