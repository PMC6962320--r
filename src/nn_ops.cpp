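// Low-level numeric kernels: same-padding 3x3 / 3x3x3 convolutions via
// im2col + GEMM, 2x2 in-plane max pooling, bilinear affine patch warping and
// nearest-grid-node assignment. All tensors are column-major R arrays.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather 3x3 neighbourhoods (zero padded) of one (H,W,C) sample into A (HW x 9C).
// Column order q = 9c + 3(dj+1) + (di+1) matches reshape(w[3,3,C,K], 9C, K).
static void im2col2d(const double* x, int H, int W, int C, arma::mat& A) {
  A.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int q = c * 9 + (dj + 1) * 3 + (di + 1);
        double* Acol = A.colptr(q);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const double* xcol = xc + (size_t)sj * H;
          double* arow = Acol + (size_t)j * H;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) arow[i] = xcol[i + di];
        }
      }
    }
  }
}

// Scatter-add transpose of im2col2d.
static void col2im2d(const arma::mat& G, int H, int W, int C, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int q = c * 9 + (dj + 1) * 3 + (di + 1);
        const double* Acol = G.colptr(q);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          double* xcol = xc + (size_t)sj * H;
          const double* arow = Acol + (size_t)j * H;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) xcol[i + di] += arow[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"); // H W C N
  IntegerVector wd = w.attr("dim"); // 3 3 C K
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], K = wd[3];
  arma::mat Wm(w.begin(), 9 * C, K, false);
  arma::rowvec bv(b.begin(), K, false);
  NumericVector y((R_xlen_t)H * W * K * N);
  y.attr("dim") = IntegerVector::create(H, W, K, N);
  arma::mat A((size_t)H * W, 9 * C);
  for (int s = 0; s < N; ++s) {
    im2col2d(x.begin() + (size_t)s * H * W * C, H, W, C, A);
    arma::mat Y(y.begin() + (size_t)s * H * W * K, (size_t)H * W, K, false, true);
    Y = A * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], K = wd[3];
  arma::mat Wm(w.begin(), 9 * C, K, false);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)9 * C * K);
  dw.attr("dim") = IntegerVector::create(3, 3, C, K);
  NumericVector db(K);
  arma::mat dWm(dw.begin(), 9 * C, K, false, true);
  arma::rowvec dbv(db.begin(), K, false, true);
  arma::mat A((size_t)H * W, 9 * C), G;
  for (int s = 0; s < N; ++s) {
    im2col2d(x.begin() + (size_t)s * H * W * C, H, W, C, A);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)s * H * W * K,
                 (size_t)H * W, K, false);
    dWm += A.t() * dY;
    dbv += arma::sum(dY, 0);
    G = dY * Wm.t();
    col2im2d(G, H, W, C, dx.begin() + (size_t)s * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 3x3x3 analogue: A is (HWD x 27C), q = 27c + 9(dk+1) + 3(dj+1) + (di+1).
static void im2col3d(const double* x, int H, int W, int D, int C, arma::mat& A) {
  A.zeros();
  size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW * D;
    for (int dk = -1; dk <= 1; ++dk) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          int q = c * 27 + (dk + 1) * 9 + (dj + 1) * 3 + (di + 1);
          double* Acol = A.colptr(q);
          for (int k = 0; k < D; ++k) {
            int sk = k + dk;
            if (sk < 0 || sk >= D) continue;
            const double* xk = xc + (size_t)sk * HW;
            double* ak = Acol + (size_t)k * HW;
            for (int j = 0; j < W; ++j) {
              int sj = j + dj;
              if (sj < 0 || sj >= W) continue;
              const double* xcol = xk + (size_t)sj * H;
              double* arow = ak + (size_t)j * H;
              int i0 = std::max(0, -di), i1 = std::min(H, H - di);
              for (int i = i0; i < i1; ++i) arow[i] = xcol[i + di];
            }
          }
        }
      }
    }
  }
}

static void col2im3d(const arma::mat& G, int H, int W, int D, int C, double* dx) {
  size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * HW * D;
    for (int dk = -1; dk <= 1; ++dk) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          int q = c * 27 + (dk + 1) * 9 + (dj + 1) * 3 + (di + 1);
          const double* Acol = G.colptr(q);
          for (int k = 0; k < D; ++k) {
            int sk = k + dk;
            if (sk < 0 || sk >= D) continue;
            double* xk = xc + (size_t)sk * HW;
            const double* ak = Acol + (size_t)k * HW;
            for (int j = 0; j < W; ++j) {
              int sj = j + dj;
              if (sj < 0 || sj >= W) continue;
              double* xcol = xk + (size_t)sj * H;
              const double* arow = ak + (size_t)j * H;
              int i0 = std::max(0, -di), i1 = std::min(H, H - di);
              for (int i = i0; i < i1; ++i) xcol[i + di] += arow[i];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"); // H W D C N
  IntegerVector wd = w.attr("dim"); // 3 3 3 C K
  int H = xd[0], W = xd[1], D = xd[2], C = xd[3], N = xd[4], K = wd[4];
  arma::mat Wm(w.begin(), 27 * C, K, false);
  arma::rowvec bv(b.begin(), K, false);
  NumericVector y((R_xlen_t)H * W * D * K * N);
  y.attr("dim") = IntegerVector::create(H, W, D, K, N);
  arma::mat A((size_t)H * W * D, 27 * C);
  for (int s = 0; s < N; ++s) {
    im2col3d(x.begin() + (size_t)s * H * W * D * C, H, W, D, C, A);
    arma::mat Y(y.begin() + (size_t)s * H * W * D * K, (size_t)H * W * D, K, false, true);
    Y = A * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], D = xd[2], C = xd[3], N = xd[4], K = wd[4];
  arma::mat Wm(w.begin(), 27 * C, K, false);
  NumericVector dx((R_xlen_t)H * W * D * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, D, C, N);
  NumericVector dw((R_xlen_t)27 * C * K);
  dw.attr("dim") = IntegerVector::create(3, 3, 3, C, K);
  NumericVector db(K);
  arma::mat dWm(dw.begin(), 27 * C, K, false, true);
  arma::rowvec dbv(db.begin(), K, false, true);
  arma::mat A((size_t)H * W * D, 27 * C), G;
  for (int s = 0; s < N; ++s) {
    im2col3d(x.begin() + (size_t)s * H * W * D * C, H, W, D, C, A);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)s * H * W * D * K,
                 (size_t)H * W * D, K, false);
    dWm += A.t() * dY;
    dbv += arma::sum(dY, 0);
    G = dY * Wm.t();
    col2im3d(G, H, W, D, C, dx.begin() + (size_t)s * H * W * D * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 (stride 2) max pooling over the first two array dimensions; all trailing
// dimensions are treated as independent slices. Returns pooled values plus the
// 0-based linear argmax index into x for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_hw_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1];
  size_t M = 1;
  for (int d = 2; d < xd.size(); ++d) M *= xd[d];
  int Ho = H / 2, Wo = W / 2;
  IntegerVector yd = clone(xd);
  yd[0] = Ho; yd[1] = Wo;
  R_xlen_t ylen = (R_xlen_t)Ho * Wo * M;
  NumericVector y(ylen);
  y.attr("dim") = yd;
  IntegerVector idx(ylen);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (size_t m = 0; m < M; ++m) {
    size_t xoff = m * (size_t)H * W;
    size_t yoff = m * (size_t)Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        size_t base = xoff + (size_t)(2 * j) * H + 2 * i;
        size_t best = base;
        double bv = xp[base];
        size_t cand[3] = {base + 1, base + H, base + H + 1};
        for (int t = 0; t < 3; ++t)
          if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
        size_t yi = yoff + (size_t)j * Ho + i;
        yp[yi] = bv;
        ip[yi] = (int)best;
      }
    }
  }
  idx.attr("dim") = yd;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_hw_bwd(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  size_t n = 1;
  for (int d = 0; d < xdim.size(); ++d) n *= xdim[d];
  NumericVector dx((R_xlen_t)n);
  const int* ip = idx.begin();
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (R_xlen_t t = 0; t < dy.size(); ++t) xp[ip[t]] += dp[t];
  dx.attr("dim") = xdim;
  return dx;
}

static inline double reflect_coord(double v, int n) {
  if (n == 1) return 0.0;
  double period = 2.0 * (n - 1);
  v -= std::floor(v / period) * period;   // wrap into [0, period)
  return (v > n - 1) ? period - v : v;
}

// Bilinear resampling of a 2D image under an inverse affine map: the source
// coordinate of output pixel (i, j) (0-based) is M %*% c(i, j, 1). Out-of-range
// source coordinates are mirror-reflected about the image edges.
// [[Rcpp::export]]
NumericMatrix cpp_affine_warp2d(NumericMatrix img, NumericMatrix M) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double si = M(0, 0) * i + M(0, 1) * j + M(0, 2);
      double sj = M(1, 0) * i + M(1, 1) * j + M(1, 2);
      si = reflect_coord(si, H);
      sj = reflect_coord(sj, W);
      int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      double fi = si - i0, fj = sj - j0;
      out(i, j) = (1 - fi) * (1 - fj) * img(i0, j0) + fi * (1 - fj) * img(i1, j0) +
                  (1 - fi) * fj * img(i0, j1) + fi * fj * img(i1, j1);
    }
  }
  return out;
}

// For every in-mask voxel, the index (1-based) of the nearest classified grid
// node in voxel-unit Euclidean distance; ties keep the lowest node index.
// nodes: n x 3 matrix of 1-based voxel coordinates. Returns 0 outside the mask.
// [[Rcpp::export]]
IntegerVector cpp_nearest_node(IntegerVector mask, IntegerVector dims, NumericMatrix nodes) {
  int H = dims[0], W = dims[1], D = dims[2];
  int n = nodes.nrow();
  IntegerVector out(mask.size());
  const int* mp = mask.begin();
  int* op = out.begin();
  std::vector<double> ni(n), nj(n), nk(n);
  for (int t = 0; t < n; ++t) {
    ni[t] = nodes(t, 0); nj[t] = nodes(t, 1); nk[t] = nodes(t, 2);
  }
  size_t v = 0;
  for (int k = 1; k <= D; ++k) {
    for (int j = 1; j <= W; ++j) {
      for (int i = 1; i <= H; ++i, ++v) {
        if (!mp[v]) { op[v] = 0; continue; }
        double best = R_PosInf;
        int arg = 0;
        for (int t = 0; t < n; ++t) {
          double di = i - ni[t], dj = j - nj[t], dk = k - nk[t];
          double d2 = di * di + dj * dj + dk * dk;
          if (d2 < best) { best = d2; arg = t + 1; }
        }
        op[v] = arg;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
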