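#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, N, C), column-major (channel-last so
// that matrix views over (H*W*N, C) are reshape-free).
// im2col lowers a batch of images to a matrix with
//   rows:    ho + Ho*(wo + Wo*n)            (output pixel, batch-major last)
//   columns: ki + kh*(kj + kw*c)            (kernel tap, channel-major last)
// so that convolution is a single GEMM against a (kh*kw*C) x Cout weight
// matrix.  Out-of-canvas taps read as zero (zero padding).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C,
                         int kh, int kw, int stride, int dil, int pad,
                         int Ho, int Wo) {
  NumericMatrix out(Ho * Wo * N, kh * kw * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * c);
        double *pcol = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double *pim = px + ((R_xlen_t)c * N + n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj * dil;
            double *pdst = pcol + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) pdst[ho] = 0.0;
            } else {
              const double *psrc = pim + (R_xlen_t)wi * H;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + ki * dil;
                pdst[ho] = (hi < 0 || hi >= H) ? 0.0 : psrc[hi];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-adds the lowered matrix back onto the
// (H, W, N, C) canvas.  Used for conv input gradients and for the forward
// pass of stride-2 transposed convolutions.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int N, int C,
                         int kh, int kw, int stride, int dil, int pad,
                         int Ho, int Wo) {
  NumericVector x((R_xlen_t)H * W * C * N);
  double *px = x.begin();
  const double *po = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * c);
        const double *pcol = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          double *pim = px + ((R_xlen_t)c * N + n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj * dil;
            if (wi < 0 || wi >= W) continue;
            const double *psrc = pcol + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            double *pdst = pim + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki * dil;
              if (hi >= 0 && hi < H) pdst[hi] += psrc[ho];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, N, C);
  return x;
}

// Max-combine an amplitude disk into the vessel contrast profile.

// [[Rcpp::export]]
void stamp_amp_cpp(NumericMatrix profile, double row, double col, double r,
                   double amp) {
  const int H = profile.nrow(), W = profile.ncol();
  const int r0 = std::max(0, (int)std::floor(row - r) - 1);
  const int r1 = std::min(H - 1, (int)std::ceil(row + r));
  const int c0 = std::max(0, (int)std::floor(col - r) - 1);
  const int c1 = std::min(W - 1, (int)std::ceil(col + r));
  const double r2 = r * r;
  for (int j = c0; j <= c1; ++j) {
    const double dc = (j + 1) - col;
    for (int i = r0; i <= r1; ++i) {
      const double dr = (i + 1) - row;
      if (dr * dr + dc * dc <= r2 && profile(i, j) < amp) profile(i, j) = amp;
    }
  }
}

// Disk stamping for the synthetic vessel renderer: set mask pixels within
// radius r of (row, col) (1-based centre coordinates, fractional allowed).

// [[Rcpp::export]]
void stamp_disk_cpp(NumericMatrix mask, double row, double col, double r) {
  const int H = mask.nrow(), W = mask.ncol();
  const int r0 = std::max(0, (int)std::floor(row - r) - 1);
  const int r1 = std::min(H - 1, (int)std::ceil(row + r));
  const int c0 = std::max(0, (int)std::floor(col - r) - 1);
  const int c1 = std::min(W - 1, (int)std::ceil(col + r));
  const double r2 = r * r;
  for (int j = c0; j <= c1; ++j) {
    const double dc = (j + 1) - col;
    for (int i = r0; i <= r1; ++i) {
      const double dr = (i + 1) - row;
      if (dr * dr + dc * dc <= r2) mask(i, j) = 1.0;
    }
  }
}
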