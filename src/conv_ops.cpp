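#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are (H*W) x C matrices, column-major pixels: i = r + c*H
// (0-based), i.e. depth row fastest. All kernels are 3x3, zero-padded,
// stride 1, so spatial shape is preserved.

// Patch matrix layout: column (ch*9 + k) where k = (dc+1)*3 + (dr+1)
// enumerates the 3x3 offsets with dr fastest.

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& x, int H, int W) {
  const int C = x.ncol();
  NumericMatrix out(H * W, 9 * C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = &x(0, ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dc + 1) * 3 + (dr + 1);
        double* oc = &out(0, ch * 9 + k);
        for (int c = 0; c < W; ++c) {
          const int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          const int r0 = (dr < 0) ? 1 : 0;
          const int r1 = (dr > 0) ? H - 1 : H;
          const double* src = xc + cc * H + dr;
          double* dst = oc + c * H;
          for (int r = r0; r < r1; ++r) dst[r] = src[r];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch gradients back onto the image grid.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& dpatch, int H, int W, int C) {
  NumericMatrix dx(H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    double* xc = &dx(0, ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dc + 1) * 3 + (dr + 1);
        const double* oc = &dpatch(0, ch * 9 + k);
        for (int c = 0; c < W; ++c) {
          const int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          const int r0 = (dr < 0) ? 1 : 0;
          const int r1 = (dr > 0) ? H - 1 : H;
          double* dst = xc + cc * H + dr;
          const double* src = oc + c * H;
          for (int r = r0; r < r1; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling; requires even H and W. Returns pooled map and the
// 1-based linear indices of the winning input pixels (ties -> first).
// [[Rcpp::export]]
List maxpool2(const NumericMatrix& x, int H, int W) {
  const int C = x.ncol(), Ho = H / 2, Wo = W / 2;
  NumericMatrix out(Ho * Wo, C);
  IntegerMatrix arg(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = &x(0, ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        int best = (2 * c) * H + 2 * r;
        double bv = xc[best];
        const int cand[3] = {best + 1, best + H, best + H + 1};
        for (int j = 0; j < 3; ++j)
          if (xc[cand[j]] > bv) { bv = xc[cand[j]]; best = cand[j]; }
        out(c * Ho + r, ch) = bv;
        arg(c * Ho + r, ch) = best + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_bwd(const NumericMatrix& dout, const IntegerMatrix& arg,
                           int H, int W) {
  const int C = dout.ncol();
  NumericMatrix dx(H * W, C);
  for (int ch = 0; ch < C; ++ch)
    for (int i = 0; i < dout.nrow(); ++i)
      dx(arg(i, ch) - 1, ch) += dout(i, ch);
  return dx;
}

// Nearest-neighbour 2x upsampling from an (H x W) grid to (2H x 2W).
// [[Rcpp::export]]
NumericMatrix upsample2(const NumericMatrix& x, int H, int W) {
  const int C = x.ncol(), Ho = 2 * H;
  NumericMatrix out(4 * H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = &x(0, ch);
    double* oc = &out(0, ch);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const double v = xc[c * H + r];
        const int base = (2 * c) * Ho + 2 * r;
        oc[base] = v; oc[base + 1] = v;
        oc[base + Ho] = v; oc[base + Ho + 1] = v;
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix upsample2_bwd(const NumericMatrix& dout, int H, int W) {
  const int C = dout.ncol(), Ho = 2 * H;
  NumericMatrix dx(H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* oc = &dout(0, ch);
    double* xc = &dx(0, ch);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const int base = (2 * c) * Ho + 2 * r;
        xc[c * H + r] = oc[base] + oc[base + 1] + oc[base + Ho] + oc[base + Ho + 1];
      }
  }
  return dx;
}
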