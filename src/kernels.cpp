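#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Volumes/feature maps are column-major arrays [nx, ny, nz, C]; x varies fastest.
// im2col unrolls k x k x k neighbourhoods (zero padding (k-1)/2, stride 1) into a
// [nvox, C*k^3] matrix so convolution becomes one BLAS GEMM.

// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, int nx, int ny, int nz, int cin, int k) {
  const int k3 = k * k * k, p = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(nvox, (R_xlen_t)cin * k3);
  for (int c = 0; c < cin; ++c) {
    const double* xc = &x[(R_xlen_t)c * nvox];
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = c * k3 + (kz * k + ky) * k + kx;
          double* oc = &out(0, col);
          const int dz = kz - p, dy = ky - p, dx = kx - p;
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int z = 0; z < nz; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              const R_xlen_t orow = ((R_xlen_t)z * ny + y) * nx;
              const R_xlen_t srow = ((R_xlen_t)sz * ny + sy) * nx;
              for (int xx = x0; xx < x1; ++xx)
                oc[orow + xx] = xc[srow + xx + dx];
            }
          }
        }
  }
  return out;
}

// Adjoint of im2col3d: scatter-add column gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix cols, int nx, int ny, int nz, int cin, int k) {
  const int k3 = k * k * k, p = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dx_out((R_xlen_t)cin * nvox);
  for (int c = 0; c < cin; ++c) {
    double* xc = &dx_out[(R_xlen_t)c * nvox];
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = c * k3 + (kz * k + ky) * k + kx;
          const double* oc = &cols(0, col);
          const int dz = kz - p, dy = ky - p, dxo = kx - p;
          const int x0 = std::max(0, -dxo), x1 = std::min(nx, nx - dxo);
          for (int z = 0; z < nz; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              const R_xlen_t orow = ((R_xlen_t)z * ny + y) * nx;
              const R_xlen_t srow = ((R_xlen_t)sz * ny + sy) * nx;
              for (int xx = x0; xx < x1; ++xx)
                xc[srow + xx + dxo] += oc[orow + xx];
            }
          }
        }
  }
  return dx_out;
}

// 2x2x2 max pooling; returns pooled values and 0-based argmax linear indices
// into the input vector (used to route gradients in the backward pass).
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, int nx, int ny, int nz, int C) {
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const R_xlen_t nvox_in = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nvox_out = (R_xlen_t)ox * oy * oz;
  NumericVector y(nvox_out * C);
  IntegerVector idx(nvox_out * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[(R_xlen_t)c * nvox_in];
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx) {
          double best = R_NegInf;
          R_xlen_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t ii =
                    (((R_xlen_t)(2 * z + dz) * ny) + (2 * yy + dy)) * nx +
                    (2 * xx + dx);
                if (xc[ii] > best) { best = xc[ii]; bidx = ii; }
              }
          const R_xlen_t oi = (((R_xlen_t)z * oy) + yy) * ox + xx;
          y[(R_xlen_t)c * nvox_out + oi] = best;
          idx[(R_xlen_t)c * nvox_out + oi] = (int)((R_xlen_t)c * nvox_in + bidx);
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector dy, IntegerVector idx, R_xlen_t n_in) {
  NumericVector dx_out(n_in);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx_out[idx[i]] += dy[i];
  return dx_out;
}

static inline void lin_weights(int o, int n_in, int n_out, int* i0, int* i1,
                               double* w1) {
  // half-pixel (align_corners = false) source coordinate
  double s = ((double)o + 0.5) * ((double)n_in / n_out) - 0.5;
  if (s < 0) s = 0;
  if (s > n_in - 1) s = n_in - 1;
  *i0 = (int)std::floor(s);
  *i1 = std::min(*i0 + 1, n_in - 1);
  *w1 = s - *i0;
}

// Trilinear interpolation resize (used as x2 upsampling in the decoder).
// [[Rcpp::export]]
NumericVector upsample3d_fwd(NumericVector x, IntegerVector ind, IntegerVector outd,
                             int C) {
  const int nx = ind[0], ny = ind[1], nz = ind[2];
  const int ox = outd[0], oy = outd[1], oz = outd[2];
  const R_xlen_t nin = (R_xlen_t)nx * ny * nz, nout = (R_xlen_t)ox * oy * oz;
  NumericVector y(nout * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[(R_xlen_t)c * nin];
    double* yc = &y[(R_xlen_t)c * nout];
    for (int z = 0; z < oz; ++z) {
      int z0, z1; double wz;
      lin_weights(z, nz, oz, &z0, &z1, &wz);
      for (int yy = 0; yy < oy; ++yy) {
        int y0, y1; double wy;
        lin_weights(yy, ny, oy, &y0, &y1, &wy);
        for (int xx = 0; xx < ox; ++xx) {
          int x0, x1; double wx;
          lin_weights(xx, nx, ox, &x0, &x1, &wx);
          double v = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const double w = (dz ? wz : 1 - wz) * (dy ? wy : 1 - wy) *
                                 (dx ? wx : 1 - wx);
                if (w == 0.0) continue;
                v += w * xc[(((R_xlen_t)(dz ? z1 : z0) * ny) + (dy ? y1 : y0)) * nx +
                            (dx ? x1 : x0)];
              }
          yc[(((R_xlen_t)z * oy) + yy) * ox + xx] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample3d_bwd(NumericVector dy, IntegerVector ind, IntegerVector outd,
                             int C) {
  const int nx = ind[0], ny = ind[1], nz = ind[2];
  const int ox = outd[0], oy = outd[1], oz = outd[2];
  const R_xlen_t nin = (R_xlen_t)nx * ny * nz, nout = (R_xlen_t)ox * oy * oz;
  NumericVector dx_out(nin * C);
  for (int c = 0; c < C; ++c) {
    double* xc = &dx_out[(R_xlen_t)c * nin];
    const double* yc = &dy[(R_xlen_t)c * nout];
    for (int z = 0; z < oz; ++z) {
      int z0, z1; double wz;
      lin_weights(z, nz, oz, &z0, &z1, &wz);
      for (int yy = 0; yy < oy; ++yy) {
        int y0, y1; double wy;
        lin_weights(yy, ny, oy, &y0, &y1, &wy);
        for (int xx = 0; xx < ox; ++xx) {
          int x0, x1; double wx;
          lin_weights(xx, nx, ox, &x0, &x1, &wx);
          const double g = yc[(((R_xlen_t)z * oy) + yy) * ox + xx];
          for (int dz = 0; dz < 2; ++dz)
            for (int dy_ = 0; dy_ < 2; ++dy_)
              for (int dx = 0; dx < 2; ++dx) {
                const double w = (dz ? wz : 1 - wz) * (dy_ ? wy : 1 - wy) *
                                 (dx ? wx : 1 - wx);
                if (w == 0.0) continue;
                xc[(((R_xlen_t)(dz ? z1 : z0) * ny) + (dy_ ? y1 : y0)) * nx +
                   (dx ? x1 : x0)] += w * g;
              }
        }
      }
    }
  }
  return dx_out;
}

// For each point (row, physical mm coordinates) in a: min Euclidean distance to b.
// [[Rcpp::export]]
NumericVector min_dists(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- direct (im2col-free) convolution kernels ----
// Same weight layout as the im2col path: W row index = ci*k^3 + (kz*k+ky)*k+kx,
// one column per output channel. Loops are blocked by z-slice so the active
// input/output slices stay cache-resident; inner loops are contiguous x-runs.

// [[Rcpp::export]]
NumericVector conv3d_direct_fwd(NumericVector x, NumericMatrix W,
                                NumericVector b, IntegerVector dims, int cin,
                                int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int k3 = k * k * k, p = (k - 1) / 2;
  const int cout = W.ncol();
  const R_xlen_t nslice = (R_xlen_t)nx * ny, nvox = nslice * nz;
  NumericVector y(nvox * cout);
  for (int co = 0; co < cout; ++co)
    std::fill(y.begin() + (R_xlen_t)co * nvox,
              y.begin() + (R_xlen_t)(co + 1) * nvox, b[co]);
  for (int z = 0; z < nz; ++z) {
    for (int kz = 0; kz < k; ++kz) {
      const int sz = z + kz - p;
      if (sz < 0 || sz >= nz) continue;
      for (int ci = 0; ci < cin; ++ci) {
        const double* xs = &x[((R_xlen_t)ci * nz + sz) * nslice];
        for (int co = 0; co < cout; ++co) {
          double* ys = &y[((R_xlen_t)co * nz + z) * nslice];
          for (int ky = 0; ky < k; ++ky) {
            const int dy_ = ky - p;
            const int y0 = std::max(0, -dy_), y1 = std::min(ny, ny - dy_);
            for (int kx = 0; kx < k; ++kx) {
              const int dx_ = kx - p;
              const double w = W(ci * k3 + (kz * k + ky) * k + kx, co);
              if (w == 0.0) continue;
              const int x0 = std::max(0, -dx_), x1 = std::min(nx, nx - dx_);
              for (int yy = y0; yy < y1; ++yy) {
                double* yr = ys + (R_xlen_t)yy * nx;
                const double* xr = xs + (R_xlen_t)(yy + dy_) * nx + dx_;
                for (int xx = x0; xx < x1; ++xx) yr[xx] += w * xr[xx];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// Gradient w.r.t. the input: correlate dy with the transposed kernel.
// [[Rcpp::export]]
NumericVector conv3d_direct_bwd_dx(NumericVector dy, NumericMatrix W,
                                   IntegerVector dims, int cin, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int k3 = k * k * k, p = (k - 1) / 2;
  const int cout = W.ncol();
  const R_xlen_t nslice = (R_xlen_t)nx * ny, nvox = nslice * nz;
  NumericVector dx_out(nvox * cin);
  for (int z = 0; z < nz; ++z) {          // output-slice index
    for (int kz = 0; kz < k; ++kz) {
      const int sz = z + kz - p;          // source slice receiving gradient
      if (sz < 0 || sz >= nz) continue;
      for (int ci = 0; ci < cin; ++ci) {
        double* xs = &dx_out[((R_xlen_t)ci * nz + sz) * nslice];
        for (int co = 0; co < cout; ++co) {
          const double* ys = &dy[((R_xlen_t)co * nz + z) * nslice];
          for (int ky = 0; ky < k; ++ky) {
            const int dy_ = ky - p;
            const int y0 = std::max(0, -dy_), y1 = std::min(ny, ny - dy_);
            for (int kx = 0; kx < k; ++kx) {
              const int dx_ = kx - p;
              const double w = W(ci * k3 + (kz * k + ky) * k + kx, co);
              if (w == 0.0) continue;
              const int x0 = std::max(0, -dx_), x1 = std::min(nx, nx - dx_);
              for (int yy = y0; yy < y1; ++yy) {
                const double* yr = ys + (R_xlen_t)yy * nx;
                double* xr = xs + (R_xlen_t)(yy + dy_) * nx + dx_;
                for (int xx = x0; xx < x1; ++xx) xr[xx] += w * yr[xx];
              }
            }
          }
        }
      }
    }
  }
  return dx_out;
}

// Gradient w.r.t. the weights (and bias): per-offset dot products.
// [[Rcpp::export]]
List conv3d_direct_bwd_dw(NumericVector x, NumericVector dy, IntegerVector dims,
                          int cin, int cout, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int k3 = k * k * k, p = (k - 1) / 2;
  const R_xlen_t nslice = (R_xlen_t)nx * ny, nvox = nslice * nz;
  NumericMatrix dW(cin * k3, cout);
  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) {
    const double* dyc = &dy[(R_xlen_t)co * nvox];
    double s = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) s += dyc[i];
    db[co] = s;
  }
  for (int z = 0; z < nz; ++z) {
    for (int kz = 0; kz < k; ++kz) {
      const int sz = z + kz - p;
      if (sz < 0 || sz >= nz) continue;
      for (int ci = 0; ci < cin; ++ci) {
        const double* xs = &x[((R_xlen_t)ci * nz + sz) * nslice];
        for (int co = 0; co < cout; ++co) {
          const double* ys = &dy[((R_xlen_t)co * nz + z) * nslice];
          for (int ky = 0; ky < k; ++ky) {
            const int dy_ = ky - p;
            const int y0 = std::max(0, -dy_), y1 = std::min(ny, ny - dy_);
            for (int kx = 0; kx < k; ++kx) {
              const int dx_ = kx - p;
              const int x0 = std::max(0, -dx_), x1 = std::min(nx, nx - dx_);
              double acc = 0.0;
              for (int yy = y0; yy < y1; ++yy) {
                const double* yr = ys + (R_xlen_t)yy * nx;
                const double* xr = xs + (R_xlen_t)(yy + dy_) * nx + dx_;
                for (int xx = x0; xx < x1; ++xx) acc += yr[xx] * xr[xx];
              }
              dW(ci * k3 + (kz * k + ky) * k + kx, co) += acc;
            }
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}

// ---- instance norm and leaky ReLU kernels ----

// [[Rcpp::export]]
List instnorm3d_fwd(NumericVector x, R_xlen_t nvox, int C, NumericVector gamma,
                    NumericVector beta, double eps) {
  NumericVector y(nvox * C), xhat(nvox * C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[(R_xlen_t)c * nvox];
    double* yc = &y[(R_xlen_t)c * nvox];
    double* hc = &xhat[(R_xlen_t)c * nvox];
    double mu = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) mu += xc[i];
    mu /= nvox;
    double v = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      const double d = xc[i] - mu;
      v += d * d;
    }
    v /= nvox;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (R_xlen_t i = 0; i < nvox; ++i) {
      hc[i] = (xc[i] - mu) * is;
      yc[i] = g * hc[i] + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List instnorm3d_bwd(NumericVector dy, NumericVector xhat, NumericVector istd,
                    NumericVector gamma, R_xlen_t nvox, int C) {
  NumericVector dx_out(nvox * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = &dy[(R_xlen_t)c * nvox];
    const double* hc = &xhat[(R_xlen_t)c * nvox];
    double* xc = &dx_out[(R_xlen_t)c * nvox];
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      sg += dc[i] * hc[i];
      sb += dc[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], is = istd[c];
    const double m1 = g * sb / nvox, m2 = g * sg / nvox;
    for (R_xlen_t i = 0; i < nvox; ++i)
      xc[i] = is * (g * dc[i] - m1 - hc[i] * m2);
  }
  return List::create(_["dx"] = dx_out, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List lrelu3d_fwd(NumericVector x, double slope) {
  const R_xlen_t n = x.size();
  NumericVector y(n);
  LogicalVector neg(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool b = x[i] < 0;
    neg[i] = b;
    y[i] = b ? slope * x[i] : x[i];
  }
  return List::create(_["y"] = y, _["neg"] = neg);
}

// [[Rcpp::export]]
NumericVector lrelu3d_bwd(NumericVector dy, LogicalVector neg, double slope) {
  const R_xlen_t n = dy.size();
  NumericVector dx_out(n);
  for (R_xlen_t i = 0; i < n; ++i) dx_out[i] = neg[i] ? slope * dy[i] : dy[i];
  return dx_out;
}
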