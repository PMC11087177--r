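// Low-level numerical kernels: 3D convolution (im2col + GEMM), transposed
// convolution, trilinear interpolation (resampling + upsampling with exact
// adjoint), anisotropic exact Euclidean distance transform, and a linearly
// binned joint-histogram mutual-information metric.
//
// Array layout follows R: column-major, volumes indexed [x, y, z] and
// feature maps [x, y, z, c].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int X, int Y) {
  return (R_xlen_t)x + (R_xlen_t)X * ((R_xlen_t)y + (R_xlen_t)Y * (R_xlen_t)z);
}

// ---------------------------------------------------------------------------
// Trilinear / nearest-neighbour sampling at arbitrary physical points.
// pts is N x 3 (mm, in the sampled volume's physical frame). Points mapping
// outside the grid return `background`.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, int method,
                                double background) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = pts.nrow();
  NumericVector out(N);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  for (int n = 0; n < N; ++n) {
    const double vx = (pts(n, 0) - ox) / sx;
    const double vy = (pts(n, 1) - oy) / sy;
    const double vz = (pts(n, 2) - oz) / sz;
    if (method == 1) {  // nearest neighbour
      const int ix = (int)std::lround(vx);
      const int iy = (int)std::lround(vy);
      const int iz = (int)std::lround(vz);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= X || iy >= Y || iz >= Z) {
        out[n] = background;
      } else {
        out[n] = vol[idx3(ix, iy, iz, X, Y)];
      }
    } else {  // trilinear (method 2: clamp to the edge instead of filling)
      double wx = vx, wy = vy, wz = vz;
      if (method == 2) {
        wx = std::min(std::max(vx, 0.0), (double)(X - 1));
        wy = std::min(std::max(vy, 0.0), (double)(Y - 1));
        wz = std::min(std::max(vz, 0.0), (double)(Z - 1));
      } else if (vx < 0 || vy < 0 || vz < 0 || vx > X - 1 || vy > Y - 1 ||
                 vz > Z - 1) {
        out[n] = background;
        continue;
      }
      const double vx2 = wx, vy2 = wy, vz2 = wz;
      int x0 = (int)std::floor(vx2), y0 = (int)std::floor(vy2),
          z0 = (int)std::floor(vz2);
      if (x0 == X - 1) x0--;
      if (y0 == Y - 1) y0--;
      if (z0 == Z - 1) z0--;
      if (X == 1) x0 = 0;
      if (Y == 1) y0 = 0;
      if (Z == 1) z0 = 0;
      const double fx = vx2 - x0, fy = vy2 - y0, fz = vz2 - z0;
      const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
                z1 = std::min(z0 + 1, Z - 1);
      const double c000 = vol[idx3(x0, y0, z0, X, Y)];
      const double c100 = vol[idx3(x1, y0, z0, X, Y)];
      const double c010 = vol[idx3(x0, y1, z0, X, Y)];
      const double c110 = vol[idx3(x1, y1, z0, X, Y)];
      const double c001 = vol[idx3(x0, y0, z1, X, Y)];
      const double c101 = vol[idx3(x1, y0, z1, X, Y)];
      const double c011 = vol[idx3(x0, y1, z1, X, Y)];
      const double c111 = vol[idx3(x1, y1, z1, X, Y)];
      const double c00 = c000 * (1 - fx) + c100 * fx;
      const double c10 = c010 * (1 - fx) + c110 * fx;
      const double c01 = c001 * (1 - fx) + c101 * fx;
      const double c11 = c011 * (1 - fx) + c111 * fx;
      const double c0 = c00 * (1 - fy) + c10 * fy;
      const double c1 = c01 * (1 - fy) + c11 * fy;
      out[n] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared, mm^2) to the set of seed
// voxels, with anisotropic spacing: separable lower-envelope algorithm.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n,
                 double w2) {
  int k = -1;  // only finite parabolas enter the envelope
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) k--; else break;
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      zb[0] = -INFINITY;
    } else {
      k++;
      v[k] = q;
      zb[k] = s;
    }
    zb[k + 1] = INFINITY;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) k++;
    const double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector seed, IntegerVector dims,
                         NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = seed[i] ? 0.0 : INFINITY;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  double w2 = spacing[0] * spacing[0];
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      for (int x = 0; x < X; ++x) f[x] = g[idx3(x, y, z, X, Y)];
      dt1d(f, d, v, zb, X, w2);
      for (int x = 0; x < X; ++x) g[idx3(x, y, z, X, Y)] = d[x];
    }
  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      for (int y = 0; y < Y; ++y) f[y] = g[idx3(x, y, z, X, Y)];
      dt1d(f, d, v, zb, Y, w2);
      for (int y = 0; y < Y; ++y) g[idx3(x, y, z, X, Y)] = d[y];
    }
  // pass along z
  w2 = spacing[2] * spacing[2];
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      for (int z = 0; z < Z; ++z) f[z] = g[idx3(x, y, z, X, Y)];
      dt1d(f, d, v, zb, Z, w2);
      for (int z = 0; z < Z; ++z) g[idx3(x, y, z, X, Y)] = d[z];
    }
  return g;
}

// ---------------------------------------------------------------------------
// 3D convolution, kernel k (odd, "same" padding (k-1)/2 per axis), arbitrary
// per-axis stride. x: [X,Y,Z,Cin]; w: [kx,ky,kz,Cin,Cout]; b: [Cout].
static inline int out_dim(int n, int k, int s) {
  const int p = (k - 1) / 2;
  return (n + 2 * p - k) / s + 1;
}

// Fill the im2col matrix for one output z-slice.
static void fill_col(const double *x, int X, int Y, int Z, int Cin, int kx,
                     int ky, int kz, int sx, int sy, int sz, int ox, int oy,
                     int oz, arma::mat &col) {
  const int px = (kx - 1) / 2, py = (ky - 1) / 2, pz = (kz - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = x + (R_xlen_t)ci * X * Y * Z;
    for (int dz = 0; dz < kz; ++dz) {
      const int z = oz * sz - pz + dz;
      for (int dy = 0; dy < ky; ++dy) {
        for (int dx = 0; dx < kx; ++dx) {
          const int r = dx + kx * (dy + ky * (dz + kz * ci));
          double *crow = col.memptr() + r;  // stride col.n_rows
          const R_xlen_t K = col.n_rows;
          for (int iy = 0; iy < oy; ++iy) {
            const int y = iy * sy - py + dy;
            for (int ix = 0; ix < ox; ++ix) {
              const int xx = ix * sx - px + dx;
              double val = 0.0;
              if (z >= 0 && z < Z && y >= 0 && y < Y && xx >= 0 && xx < X)
                val = xc[idx3(xx, y, z, X, Y)];
              crow[(R_xlen_t)(ix + ox * iy) * K] = val;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdims,
                            NumericVector w, IntegerVector kdims,
                            NumericVector b, IntegerVector stride) {
  const int X = xdims[0], Y = xdims[1], Z = xdims[2], Cin = xdims[3];
  const int kx = kdims[0], ky = kdims[1], kz = kdims[2], Cout = kdims[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int ox = out_dim(X, kx, sx), oy = out_dim(Y, ky, sy),
            oz = out_dim(Z, kz, sz);
  const int K = kx * ky * kz * Cin;
  NumericVector y((R_xlen_t)ox * oy * oz * Cout);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat col(K, (R_xlen_t)ox * oy);
  arma::mat ys((R_xlen_t)ox * oy, Cout);
  for (int z = 0; z < oz; ++z) {
    fill_col(x.begin(), X, Y, Z, Cin, kx, ky, kz, sx, sy, sz, ox, oy, z, col);
    ys = col.t() * Wm;
    for (int co = 0; co < Cout; ++co) {
      double *yp = y.begin() + (R_xlen_t)ox * oy * (z + (R_xlen_t)oz * co);
      const double *sp = ys.colptr(co);
      const double bias = b[co];
      for (R_xlen_t m = 0; m < (R_xlen_t)ox * oy; ++m) yp[m] = sp[m] + bias;
    }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdims, NumericVector w,
                   IntegerVector kdims, NumericVector dy,
                   IntegerVector stride) {
  const int X = xdims[0], Y = xdims[1], Z = xdims[2], Cin = xdims[3];
  const int kx = kdims[0], ky = kdims[1], kz = kdims[2], Cout = kdims[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = (kx - 1) / 2, py = (ky - 1) / 2, pz = (kz - 1) / 2;
  const int ox = out_dim(X, kx, sx), oy = out_dim(Y, ky, sy),
            oz = out_dim(Z, kz, sz);
  const int K = kx * ky * kz * Cin;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector dx((R_xlen_t)X * Y * Z * Cin);
  NumericVector dwv((R_xlen_t)K * Cout);
  NumericVector dbv(Cout);
  arma::mat dW(dwv.begin(), K, Cout, false, true);
  arma::mat col(K, (R_xlen_t)ox * oy);
  arma::mat dys((R_xlen_t)ox * oy, Cout);
  arma::mat dcol(K, (R_xlen_t)ox * oy);
  for (int z = 0; z < oz; ++z) {
    fill_col(x.begin(), X, Y, Z, Cin, kx, ky, kz, sx, sy, sz, ox, oy, z, col);
    for (int co = 0; co < Cout; ++co) {
      const double *dp = dy.begin() + (R_xlen_t)ox * oy * (z + (R_xlen_t)oz * co);
      double *tp = dys.colptr(co);
      double acc = 0.0;
      for (R_xlen_t m = 0; m < (R_xlen_t)ox * oy; ++m) {
        tp[m] = dp[m];
        acc += dp[m];
      }
      dbv[co] += acc;
    }
    dW += col * dys;
    dcol = Wm * dys.t();
    // scatter col2im
    for (int ci = 0; ci < Cin; ++ci) {
      double *dxc = dx.begin() + (R_xlen_t)ci * X * Y * Z;
      for (int dz = 0; dz < kz; ++dz) {
        const int zz = z * sz - pz + dz;
        if (zz < 0 || zz >= Z) continue;
        for (int dyk = 0; dyk < ky; ++dyk) {
          for (int dxk = 0; dxk < kx; ++dxk) {
            const int r = dxk + kx * (dyk + ky * (dz + kz * ci));
            const double *crow = dcol.memptr() + r;
            const R_xlen_t Kr = dcol.n_rows;
            for (int iy = 0; iy < oy; ++iy) {
              const int yy = iy * sy - py + dyk;
              if (yy < 0 || yy >= Y) continue;
              for (int ix = 0; ix < ox; ++ix) {
                const int xx = ix * sx - px + dxk;
                if (xx < 0 || xx >= X) continue;
                dxc[idx3(xx, yy, zz, X, Y)] +=
                    crow[(R_xlen_t)(ix + ox * iy) * Kr];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  dwv.attr("dim") = IntegerVector::create(kx, ky, kz, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// ---------------------------------------------------------------------------
// Transposed convolution with kernel == stride (non-overlapping upsampling).
// x: [X,Y,Z,Cin]; w: [sx,sy,sz,Cin,Cout]; output [X*sx, Y*sy, Z*sz, Cout].
// [[Rcpp::export]]
NumericVector cpp_convT3d_fw(NumericVector x, IntegerVector xdims,
                             NumericVector w, IntegerVector stride,
                             NumericVector b, int Cout) {
  const int X = xdims[0], Y = xdims[1], Z = xdims[2], Cin = xdims[3];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int OX = X * sx, OY = Y * sy, OZ = Z * sz;
  NumericVector y((R_xlen_t)OX * OY * OZ * Cout);
  const int Ks = sx * sy * sz;
  for (int co = 0; co < Cout; ++co) {
    double *yc = y.begin() + (R_xlen_t)co * OX * OY * OZ;
    for (R_xlen_t i = 0; i < (R_xlen_t)OX * OY * OZ; ++i) yc[i] = b[co];
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = x.begin() + (R_xlen_t)ci * X * Y * Z;
      const double *wk = w.begin() + (R_xlen_t)Ks * (ci + (R_xlen_t)Cin * co);
      for (int z = 0; z < Z; ++z)
        for (int yy = 0; yy < Y; ++yy)
          for (int xx = 0; xx < X; ++xx) {
            const double v = xc[idx3(xx, yy, z, X, Y)];
            if (v == 0.0) continue;
            for (int dz = 0; dz < sz; ++dz)
              for (int dy = 0; dy < sy; ++dy)
                for (int dx = 0; dx < sx; ++dx)
                  yc[idx3(xx * sx + dx, yy * sy + dy, z * sz + dz, OX, OY)] +=
                      v * wk[dx + sx * (dy + sy * dz)];
          }
    }
  }
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_convT3d_bw(NumericVector x, IntegerVector xdims, NumericVector w,
                    IntegerVector stride, int Cout, NumericVector dy) {
  const int X = xdims[0], Y = xdims[1], Z = xdims[2], Cin = xdims[3];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int OX = X * sx, OY = Y * sy;
  const int Ks = sx * sy * sz;
  NumericVector dx((R_xlen_t)X * Y * Z * Cin);
  NumericVector dw((R_xlen_t)Ks * Cin * Cout);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double *dyc = dy.begin() + (R_xlen_t)co * OX * OY * (Z * sz);
    double acc = 0.0;
    for (R_xlen_t i = 0; i < (R_xlen_t)OX * OY * Z * sz; ++i) acc += dyc[i];
    db[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = x.begin() + (R_xlen_t)ci * X * Y * Z;
      double *dxc = dx.begin() + (R_xlen_t)ci * X * Y * Z;
      const double *wk = w.begin() + (R_xlen_t)Ks * (ci + (R_xlen_t)Cin * co);
      double *dwk = dw.begin() + (R_xlen_t)Ks * (ci + (R_xlen_t)Cin * co);
      for (int z = 0; z < Z; ++z)
        for (int yy = 0; yy < Y; ++yy)
          for (int xx = 0; xx < X; ++xx) {
            const R_xlen_t xi = idx3(xx, yy, z, X, Y);
            const double xv = xc[xi];
            double g = 0.0;
            for (int dz = 0; dz < sz; ++dz)
              for (int dyk = 0; dyk < sy; ++dyk)
                for (int dxk = 0; dxk < sx; ++dxk) {
                  const double dv = dyc[idx3(xx * sx + dxk, yy * sy + dyk,
                                             z * sz + dz, OX, OY)];
                  g += wk[dxk + sx * (dyk + sy * dz)] * dv;
                  dwk[dxk + sx * (dyk + sy * dz)] += xv * dv;
                }
            dxc[xi] += g;
          }
    }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  dw.attr("dim") = IntegerVector::create(sx, sy, sz, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Trilinear upsampling by integer factors with half-pixel alignment and its
// exact adjoint (used by the deep-supervision heads).
struct LinW {
  int i0, i1;
  double w0, w1;
};

static void axis_weights(int no, int ni, int f, std::vector<LinW> &wts) {
  wts.resize(no);
  for (int o = 0; o < no; ++o) {
    double u = (o + 0.5) / f - 0.5;
    if (u < 0) u = 0;
    if (u > ni - 1) u = ni - 1;
    int i0 = (int)std::floor(u);
    if (i0 > ni - 2) i0 = std::max(0, ni - 2);
    const double fr = u - i0;
    wts[o].i0 = i0;
    wts[o].i1 = std::min(i0 + 1, ni - 1);
    wts[o].w0 = 1 - fr;
    wts[o].w1 = fr;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample3_fw(NumericVector x, IntegerVector xdims,
                               IntegerVector factor) {
  const int X = xdims[0], Y = xdims[1], Z = xdims[2], C = xdims[3];
  const int OX = X * factor[0], OY = Y * factor[1], OZ = Z * factor[2];
  std::vector<LinW> wx, wy, wz;
  axis_weights(OX, X, factor[0], wx);
  axis_weights(OY, Y, factor[1], wy);
  axis_weights(OZ, Z, factor[2], wz);
  NumericVector y((R_xlen_t)OX * OY * OZ * C);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + (R_xlen_t)c * X * Y * Z;
    double *yc = y.begin() + (R_xlen_t)c * OX * OY * OZ;
    for (int z = 0; z < OZ; ++z)
      for (int yy = 0; yy < OY; ++yy)
        for (int xx = 0; xx < OX; ++xx) {
          const LinW &a = wx[xx], &b = wy[yy], &g = wz[z];
          double v = 0.0;
          v += g.w0 * (b.w0 * (a.w0 * xc[idx3(a.i0, b.i0, g.i0, X, Y)] +
                               a.w1 * xc[idx3(a.i1, b.i0, g.i0, X, Y)]) +
                       b.w1 * (a.w0 * xc[idx3(a.i0, b.i1, g.i0, X, Y)] +
                               a.w1 * xc[idx3(a.i1, b.i1, g.i0, X, Y)]));
          v += g.w1 * (b.w0 * (a.w0 * xc[idx3(a.i0, b.i0, g.i1, X, Y)] +
                               a.w1 * xc[idx3(a.i1, b.i0, g.i1, X, Y)]) +
                       b.w1 * (a.w0 * xc[idx3(a.i0, b.i1, g.i1, X, Y)] +
                               a.w1 * xc[idx3(a.i1, b.i1, g.i1, X, Y)]));
          yc[idx3(xx, yy, z, OX, OY)] = v;
        }
  }
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3_adj(NumericVector dy, IntegerVector xdims,
                                IntegerVector factor) {
  const int X = xdims[0], Y = xdims[1], Z = xdims[2], C = xdims[3];
  const int OX = X * factor[0], OY = Y * factor[1], OZ = Z * factor[2];
  std::vector<LinW> wx, wy, wz;
  axis_weights(OX, X, factor[0], wx);
  axis_weights(OY, Y, factor[1], wy);
  axis_weights(OZ, Z, factor[2], wz);
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  for (int c = 0; c < C; ++c) {
    double *xc = dx.begin() + (R_xlen_t)c * X * Y * Z;
    const double *yc = dy.begin() + (R_xlen_t)c * OX * OY * OZ;
    for (int z = 0; z < OZ; ++z)
      for (int yy = 0; yy < OY; ++yy)
        for (int xx = 0; xx < OX; ++xx) {
          const LinW &a = wx[xx], &b = wy[yy], &g = wz[z];
          const double v = yc[idx3(xx, yy, z, OX, OY)];
          xc[idx3(a.i0, b.i0, g.i0, X, Y)] += v * g.w0 * b.w0 * a.w0;
          xc[idx3(a.i1, b.i0, g.i0, X, Y)] += v * g.w0 * b.w0 * a.w1;
          xc[idx3(a.i0, b.i1, g.i0, X, Y)] += v * g.w0 * b.w1 * a.w0;
          xc[idx3(a.i1, b.i1, g.i0, X, Y)] += v * g.w0 * b.w1 * a.w1;
          xc[idx3(a.i0, b.i0, g.i1, X, Y)] += v * g.w1 * b.w0 * a.w0;
          xc[idx3(a.i1, b.i0, g.i1, X, Y)] += v * g.w1 * b.w0 * a.w1;
          xc[idx3(a.i0, b.i1, g.i1, X, Y)] += v * g.w1 * b.w1 * a.w0;
          xc[idx3(a.i1, b.i1, g.i1, X, Y)] += v * g.w1 * b.w1 * a.w1;
        }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return dx;
}

// ---------------------------------------------------------------------------
// Mutual information from paired intensity samples with linear (partial
// volume) binning. Pairs with non-finite moving values (out of volume) are
// dropped.
// [[Rcpp::export]]
double cpp_mi_linear(NumericVector fvals, NumericVector mvals, int nbins) {
  const int N = fvals.size();
  double fmin = R_PosInf, fmax = R_NegInf, mmin = R_PosInf, mmax = R_NegInf;
  int nvalid = 0;
  for (int i = 0; i < N; ++i) {
    if (!R_finite(mvals[i]) || !R_finite(fvals[i])) continue;
    nvalid++;
    fmin = std::min(fmin, fvals[i]);
    fmax = std::max(fmax, fvals[i]);
    mmin = std::min(mmin, mvals[i]);
    mmax = std::max(mmax, mvals[i]);
  }
  if (nvalid < 16 || fmax <= fmin || mmax <= mmin) return 0.0;
  const double fs = (nbins - 1) / (fmax - fmin);
  const double ms = (nbins - 1) / (mmax - mmin);
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  for (int i = 0; i < N; ++i) {
    if (!R_finite(mvals[i]) || !R_finite(fvals[i])) continue;
    const double bf = (fvals[i] - fmin) * fs;
    const double bm = (mvals[i] - mmin) * ms;
    int f0 = (int)std::floor(bf), m0 = (int)std::floor(bm);
    if (f0 > nbins - 2) f0 = nbins - 2;
    if (m0 > nbins - 2) m0 = nbins - 2;
    const double ff = bf - f0, fm = bm - m0;
    joint[f0 + nbins * m0] += (1 - ff) * (1 - fm);
    joint[f0 + 1 + nbins * m0] += ff * (1 - fm);
    joint[f0 + nbins * (m0 + 1)] += (1 - ff) * fm;
    joint[f0 + 1 + nbins * (m0 + 1)] += ff * fm;
  }
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  const double inv = 1.0 / nvalid;
  for (int m = 0; m < nbins; ++m)
    for (int f = 0; f < nbins; ++f) {
      joint[f + nbins * m] *= inv;
      pf[f] += joint[f + nbins * m];
      pm[m] += joint[f + nbins * m];
    }
  double mi = 0.0;
  for (int m = 0; m < nbins; ++m)
    for (int f = 0; f < nbins; ++f) {
      const double p = joint[f + nbins * m];
      if (p > 1e-12) mi += p * std::log(p / (pf[f] * pm[m]));
    }
  return mi;
}

// ---------------------------------------------------------------------------
// 6-connected component labeling (BFS). Returns 0 for background voxels and
// 1..n_components for foreground.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = cur / ((R_xlen_t)X * Y);
      const int rem = cur - (R_xlen_t)z * X * Y;
      const int y = rem / X;
      const int x = rem - y * X;
      for (int k = 0; k < 6; ++k) {
        const int nx = x + dx[k], ny = y + dy[k], nz = z + dz[k];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z)
          continue;
        const R_xlen_t ni = idx3(nx, ny, nz, X, Y);
        if (mask[ni] && !lab[ni]) {
          lab[ni] = next;
          stack.push_back(ni);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Instance normalization over the spatial axes of [X,Y,Z,C] + LReLU helpers.
// [[Rcpp::export]]
List cpp_instnorm_fw(NumericVector x, IntegerVector dims, NumericVector g,
                     NumericVector be, double eps) {
  const R_xlen_t n = (R_xlen_t)dims[0] * dims[1] * dims[2];
  const int C = dims[3];
  NumericVector y(n * C), xhat(n * C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + n * c;
    double *yc = y.begin() + n * c;
    double *hc = xhat.begin() + n * c;
    double mu = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) mu += xc[i];
    mu /= n;
    double v = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double d = xc[i] - mu;
      v += d * d;
    }
    v /= n;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    const double gc = g[c], bc = be[c];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      yc[i] = gc * h + bc;
    }
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_instnorm_bw(NumericVector dy, NumericVector xhat,
                     NumericVector istd, NumericVector g,
                     IntegerVector dims) {
  const R_xlen_t n = (R_xlen_t)dims[0] * dims[1] * dims[2];
  const int C = dims[3];
  NumericVector dx(n * C), dg(C), dbe(C);
  for (int c = 0; c < C; ++c) {
    const double *dyc = dy.begin() + n * c;
    const double *hc = xhat.begin() + n * c;
    double *dxc = dx.begin() + n * c;
    double s1 = 0.0, s2 = 0.0, sdg = 0.0, sdb = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double dh = dyc[i] * g[c];
      s1 += dh;
      s2 += dh * hc[i];
      sdg += dyc[i] * hc[i];
      sdb += dyc[i];
    }
    dg[c] = sdg;
    dbe[c] = sdb;
    const double m1 = s1 / n, m2 = s2 / n, is = istd[c], gc = g[c];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double dh = dyc[i] * gc;
      dxc[i] = is * (dh - m1 - hc[i] * m2);
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dg"] = dg, _["dbe"] = dbe);
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fw(NumericVector x, double alpha) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : alpha * x[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bw(NumericVector dy, NumericVector y,
                           double alpha) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[i] = y[i] > 0 ? dy[i] : alpha * dy[i];
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
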