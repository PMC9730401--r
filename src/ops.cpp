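#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensors cross the R boundary as base arrays in (H, W, C, N) layout
// (column-major, so each (H x W) channel plane is contiguous). Convolution
// uses im2col + BLAS gemm, chunked over image columns to bound the scratch
// buffer. Stride is fixed at 1; `pad` is symmetric zero padding (1 for the
// 3x3 blocks, 0 for 1x1 projections).

static void im2col_chunk(const double* x, int H, int W, int Cin,
                         int k, int pad, int j0, int jc, arma::mat& col) {
  const int rows = k * k * Cin;
  col.zeros();
  for (int jj = 0; jj < jc; jj++) {
    const int j = j0 + jj;
    for (int c = 0; c < Cin; c++) {
      const double* xc = x + (size_t)H * W * c;
      for (int q = 0; q < k; q++) {
        const int js = j + q - pad;
        if (js < 0 || js >= W) continue;
        const double* xcol = xc + (size_t)H * js;
        for (int p = 0; p < k; p++) {
          const int r = p + k * q + k * k * c;
          const int ilo = std::max(0, pad - p);
          const int ihi = std::min(H - 1, H - 1 + pad - p);
          double* cp = col.memptr() + r;
          for (int i = ilo; i <= ihi; i++)
            cp[(size_t)(jj * H + i) * rows] = xcol[i + p - pad];
        }
      }
    }
  }
}

static int chunk_cols(int rows, int H, int W) {
  int chunk = (int)(2000000.0 / ((double)rows * H));
  if (chunk < 1) chunk = 1;
  if (chunk > W) chunk = W;
  return chunk;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight dims inconsistent with input");
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  const int rows = k * k * Cin;
  const int chunk = chunk_cols(rows, H, W);
  for (int n = 0; n < N; n++) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    for (int j0 = 0; j0 < W; j0 += chunk) {
      const int jc = std::min(chunk, W - j0);
      arma::mat col(rows, (size_t)H * jc);
      im2col_chunk(xn, H, W, Cin, k, pad, j0, jc, col);
      arma::mat yc = col.t() * Wm;  // (H*jc) x Cout
      for (int o = 0; o < Cout; o++) {
        double* yp = y.begin() + (size_t)H * W * (o + (size_t)Cout * n) + (size_t)H * j0;
        const double* src = yc.colptr(o);
        const double bo = b[o];
        for (int t = 0; t < H * jc; t++) yp[t] = src[t] + bo;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  NumericVector gx((size_t)H * W * Cin * N), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat Gw(gw.begin(), k * k * Cin, Cout, false, true);
  const int rows = k * k * Cin;
  const int chunk = chunk_cols(rows, H, W);
  for (int n = 0; n < N; n++) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    double* gxn = gx.begin() + (size_t)H * W * Cin * n;
    for (int j0 = 0; j0 < W; j0 += chunk) {
      const int jc = std::min(chunk, W - j0);
      arma::mat col(rows, (size_t)H * jc);
      arma::mat gyc((size_t)H * jc, Cout);
      im2col_chunk(xn, H, W, Cin, k, pad, j0, jc, col);
      for (int o = 0; o < Cout; o++) {
        const double* gp = gy.begin() + (size_t)H * W * (o + (size_t)Cout * n) + (size_t)H * j0;
        std::copy(gp, gp + (size_t)H * jc, gyc.colptr(o));
        gb[o] += std::accumulate(gp, gp + (size_t)H * jc, 0.0);
      }
      Gw += col * gyc;
      arma::mat gcol = Wm * gyc.t();  // rows x (H*jc)
      // col2im scatter-add (reverse of im2col_chunk)
      for (int jj = 0; jj < jc; jj++) {
        const int j = j0 + jj;
        for (int c = 0; c < Cin; c++) {
          double* gxc = gxn + (size_t)H * W * c;
          for (int q = 0; q < k; q++) {
            const int js = j + q - pad;
            if (js < 0 || js >= W) continue;
            double* gxcol = gxc + (size_t)H * js;
            for (int p = 0; p < k; p++) {
              const int r = p + k * q + k * k * c;
              const int ilo = std::max(0, pad - p);
              const int ihi = std::min(H - 1, H - 1 + pad - p);
              const double* cp = gcol.memptr() + r;
              for (int i = ilo; i <= ihi; i++)
                gxcol[i + p - pad] += cp[(size_t)(jj * H + i) * rows];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and the 0-based linear
// index of each argmax within its input (H x W) plane, for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  size_t t = 0;
  for (int cn = 0; cn < C * N; cn++) {
    const double* xp = x.begin() + (size_t)H * W * cn;
    for (int jo = 0; jo < Wo; jo++) {
      for (int io = 0; io < Ho; io++, t++) {
        const int i = 2 * io, j = 2 * jo;
        int best = i + H * j;
        double bv = xp[best];
        const int cand[3] = { i + 1 + H * j, i + H * (j + 1), i + 1 + H * (j + 1) };
        for (int u = 0; u < 3; u++)
          if (xp[cand[u]] > bv) { bv = xp[cand[u]]; best = cand[u]; }
        y[t] = bv;
        idx[t] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(IntegerVector idx, NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t t = 0;
  for (int cn = 0; cn < C * N; cn++) {
    double* gp = gx.begin() + (size_t)H * W * cn;
    for (size_t u = 0; u < (size_t)Ho * Wo; u++, t++) gp[idx[t]] += gy[t];
  }
  return gx;
}

struct LinWeights {
  std::vector<int> i0, i1;
  std::vector<double> w1;  // weight on i1; (1-w1) on i0
};

static LinWeights lin_weights(int nin, int nout) {
  LinWeights lw;
  lw.i0.resize(nout); lw.i1.resize(nout); lw.w1.resize(nout);
  const double scale = (double)nin / nout;
  for (int o = 0; o < nout; o++) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > nin - 1) s = nin - 1;
    const int i0 = (int)std::floor(s);
    const int i1 = std::min(i0 + 1, nin - 1);
    lw.i0[o] = i0; lw.i1[o] = i1; lw.w1[o] = s - i0;
  }
  return lw;
}

// Bilinear resize (half-pixel centers, edges clamped), per channel plane.
// [[Rcpp::export]]
NumericVector resize_bilinear_fwd_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  LinWeights rw = lin_weights(H, Ho), cw = lin_weights(W, Wo);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t t = 0;
  for (int cn = 0; cn < C * N; cn++) {
    const double* xp = x.begin() + (size_t)H * W * cn;
    for (int jo = 0; jo < Wo; jo++) {
      const double* c0 = xp + (size_t)H * cw.i0[jo];
      const double* c1 = xp + (size_t)H * cw.i1[jo];
      const double wj = cw.w1[jo];
      for (int io = 0; io < Ho; io++, t++) {
        const int i0 = rw.i0[io], i1 = rw.i1[io];
        const double wi = rw.w1[io];
        const double top = (1 - wj) * c0[i0] + wj * c1[i0];
        const double bot = (1 - wj) * c0[i1] + wj * c1[i1];
        y[t] = (1 - wi) * top + wi * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bwd_cpp(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  LinWeights rw = lin_weights(H, Ho), cw = lin_weights(W, Wo);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t t = 0;
  for (int cn = 0; cn < C * N; cn++) {
    double* gp = gx.begin() + (size_t)H * W * cn;
    for (int jo = 0; jo < Wo; jo++) {
      double* c0 = gp + (size_t)H * cw.i0[jo];
      double* c1 = gp + (size_t)H * cw.i1[jo];
      const double wj = cw.w1[jo];
      for (int io = 0; io < Ho; io++, t++) {
        const int i0 = rw.i0[io], i1 = rw.i1[io];
        const double wi = rw.w1[io], g = gy[t];
        c0[i0] += g * (1 - wi) * (1 - wj);
        c1[i0] += g * (1 - wi) * wj;
        c0[i1] += g * wi * (1 - wj);
        c1[i1] += g * wi * wj;
      }
    }
  }
  return gx;
}

// For each point (row) of `a`, the minimum Euclidean distance to any row of
// `b`. Points are physical (mm) coordinates; used for surface distances.
// [[Rcpp::export]]
NumericVector min_point_dists_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    for (int j = 0; j < m; j++) {
      double s = 0;
      for (int k = 0; k < d; k++) {
        const double dv = a(i, k) - b(j, k);
        s += dv * dv;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
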