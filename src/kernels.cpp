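// Numeric kernels: im2col/col2im convolution support, max pooling,
// 3-D connected components, ball morphology, trilinear resampling.
// Array layout follows R column-major conventions throughout:
// images are (H, W, C, N), volumes are (nx, ny, nz).
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unfold a batch (H,W,C,N) into a (K*K*C) x (Ho*Wo*N) matrix.
// Row index r = ki + K*(kj + K*c); column index m = ho + Ho*(wo + Wo*n).
// [[Rcpp::export]]
arma::mat im2col_batch(const NumericVector& x, int H, int W, int C, int N,
                       int K, int stride, int pad) {
  const int Ho = out_extent(H, K, stride, pad);
  const int Wo = out_extent(W, K, stride, pad);
  arma::mat cols(K * K * C, (size_t)Ho * Wo * N, arma::fill::zeros);
  const double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t m = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        double* col = cols.colptr(m);
        for (int c = 0; c < C; ++c) {
          const size_t base = ((size_t)c + (size_t)C * n) * H * W;
          for (int kj = 0; kj < K; ++kj) {
            const int wj = wo * stride - pad + kj;
            for (int ki = 0; ki < K; ++ki) {
              const int hi = ho * stride - pad + ki;
              const int r = ki + K * (kj + K * c);
              if (hi >= 0 && hi < H && wj >= 0 && wj < W)
                col[r] = px[base + (size_t)hi + (size_t)H * wj];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Fold gradients back: inverse scatter-add of im2col_batch.
// [[Rcpp::export]]
NumericVector col2im_batch(const arma::mat& cols, int H, int W, int C, int N,
                           int K, int stride, int pad) {
  const int Ho = out_extent(H, K, stride, pad);
  const int Wo = out_extent(W, K, stride, pad);
  NumericVector dx((size_t)H * W * C * N);
  double* pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t m = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        const double* col = cols.colptr(m);
        for (int c = 0; c < C; ++c) {
          const size_t base = ((size_t)c + (size_t)C * n) * H * W;
          for (int kj = 0; kj < K; ++kj) {
            const int wj = wo * stride - pad + kj;
            for (int ki = 0; ki < K; ++ki) {
              const int hi = ho * stride - pad + ki;
              const int r = ki + K * (kj + K * c);
              if (hi >= 0 && hi < H && wj >= 0 && wj < W)
                pdx[base + (size_t)hi + (size_t)H * wj] += col[r];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Max pooling over KxK windows. Returns the pooled batch and, for the
// backward pass, the 1-based linear index of each selected input element.
// [[Rcpp::export]]
List maxpool_fw(const NumericVector& x, int H, int W, int C, int N,
                int K, int stride, int pad) {
  const int Ho = out_extent(H, K, stride, pad);
  const int Wo = out_extent(W, K, stride, pad);
  const size_t M = (size_t)Ho * Wo * C * N;
  NumericVector out(M);
  IntegerVector idx(M);
  const double* px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)c + (size_t)C * n) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; size_t bidx = 0;
          for (int kj = 0; kj < K; ++kj) {
            const int wj = wo * stride - pad + kj;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const size_t li = base + (size_t)hi + (size_t)H * wj;
              if (px[li] > best) { best = px[li]; bidx = li; }
            }
          }
          const size_t mo = (size_t)ho + (size_t)Ho *
            (wo + (size_t)Wo * (c + (size_t)C * n));
          out[mo] = best;
          idx[mo] = (int)(bidx + 1);
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(const NumericVector& dy, const IntegerVector& idx,
                         int H, int W, int C, int N) {
  NumericVector dx((size_t)H * W * C * N);
  for (R_xlen_t m = 0; m < dy.size(); ++m) dx[idx[m] - 1] += dy[m];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// 6-connected component labelling of a logical 3-D array.
// [[Rcpp::export]]
IntegerVector cc_label_3d(const LogicalVector& v, int nx, int ny, int nz) {
  IntegerVector lab((size_t)nx * ny * nz);
  const int dx[6] = { 1, -1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, 1, -1, 0, 0 };
  const int dz[6] = { 0, 0, 0, 0, 1, -1 };
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < (size_t)v.size(); ++s) {
    if (!v[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const size_t cur = q.front(); q.pop();
      const int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int d = 0; d < 6; ++d) {
        const int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const size_t t = (size_t)ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (v[t] && !lab[t]) { lab[t] = next; q.push(t); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}

static LogicalVector morph_ball(const LogicalVector& v, int nx, int ny, int nz,
                                double radius, bool dilate) {
  std::vector<int> ox, oy, oz;
  const int r = (int)std::floor(radius);
  for (int k = -r; k <= r; ++k)
    for (int j = -r; j <= r; ++j)
      for (int i = -r; i <= r; ++i)
        if (i * i + j * j + k * k <= radius * radius) {
          ox.push_back(i); oy.push_back(j); oz.push_back(k);
        }
  LogicalVector out((size_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t s = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        bool val = dilate ? false : true;
        for (size_t d = 0; d < ox.size(); ++d) {
          const int ii = i + ox[d], jj = j + oy[d], kk = k + oz[d];
          bool inb = ii >= 0 && ii < nx && jj >= 0 && jj < ny &&
                     kk >= 0 && kk < nz;
          bool nb = inb ? (bool)v[(size_t)ii + (size_t)nx *
                                  (jj + (size_t)ny * kk)] : false;
          if (dilate) { if (nb) { val = true; break; } }
          else        { if (!nb) { val = false; break; } }
        }
        out[s] = val;
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// [[Rcpp::export]]
LogicalVector dilate_ball_3d(const LogicalVector& v, int nx, int ny, int nz,
                             double radius) {
  return morph_ball(v, nx, ny, nz, radius, true);
}

// [[Rcpp::export]]
LogicalVector erode_ball_3d(const LogicalVector& v, int nx, int ny, int nz,
                            double radius) {
  return morph_ball(v, nx, ny, nz, radius, false);
}

// Resample a volume under a rigid rotation about its physical center with
// trilinear interpolation; rinv maps output physical coordinates back into
// input physical coordinates. Out-of-field voxels take `fill`.
// [[Rcpp::export]]
NumericVector rotate_resample_3d(const NumericVector& v, int nx, int ny, int nz,
                                 const NumericVector& spacing,
                                 const NumericMatrix& rinv, double fill) {
  NumericVector out((size_t)nx * ny * nz);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double cx = sx * (nx - 1) / 2.0, cy = sy * (ny - 1) / 2.0,
               cz = sz * (nz - 1) / 2.0;
  const double* pv = v.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double px = i * sx - cx, py = j * sy - cy, pz = k * sz - cz;
        const double qx = rinv(0, 0) * px + rinv(0, 1) * py + rinv(0, 2) * pz;
        const double qy = rinv(1, 0) * px + rinv(1, 1) * py + rinv(1, 2) * pz;
        const double qz = rinv(2, 0) * px + rinv(2, 1) * py + rinv(2, 2) * pz;
        const double fx = (qx + cx) / sx, fy = (qy + cy) / sy,
                     fz = (qz + cz) / sz;
        const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
                  z0 = (int)std::floor(fz);
        const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
        double acc = 0.0;
        for (int dz2 = 0; dz2 <= 1; ++dz2)
          for (int dy2 = 0; dy2 <= 1; ++dy2)
            for (int dx2 = 0; dx2 <= 1; ++dx2) {
              const int xi = x0 + dx2, yi = y0 + dy2, zi = z0 + dz2;
              const double w = (dx2 ? tx : 1 - tx) * (dy2 ? ty : 1 - ty) *
                               (dz2 ? tz : 1 - tz);
              double val = fill;
              if (xi >= 0 && xi < nx && yi >= 0 && yi < ny &&
                  zi >= 0 && zi < nz)
                val = pv[(size_t)xi + (size_t)nx * (yi + (size_t)ny * zi)];
              acc += w * val;
            }
        out[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = acc;
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Bilinear resize of a matrix with half-pixel center alignment.
// [[Rcpp::export]]
NumericMatrix resize_bilinear_2d(const NumericMatrix& x, int oh, int ow) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(oh, ow);
  const double sh = (double)H / oh, sw = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double fy = (j + 0.5) * sw - 0.5;
    int y0 = (int)std::floor(fy);
    double ty = fy - y0;
    int y1 = std::min(std::max(y0 + 1, 0), W - 1);
    y0 = std::min(std::max(y0, 0), W - 1);
    for (int i = 0; i < oh; ++i) {
      double fx = (i + 0.5) * sh - 0.5;
      int x0 = (int)std::floor(fx);
      double tx = fx - x0;
      int x1 = std::min(std::max(x0 + 1, 0), H - 1);
      x0 = std::min(std::max(x0, 0), H - 1);
      out(i, j) = (1 - tx) * (1 - ty) * x(x0, y0) + tx * (1 - ty) * x(x1, y0) +
                  (1 - tx) * ty * x(x0, y1) + tx * ty * x(x1, y1);
    }
  }
  return out;
}
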