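// Dense array kernels backing the autodiff tape: 3D convolution,
// clamped shifts, box sums, trilinear warping, distance transforms.
// All arrays are double, column-major, spatial-first layout
// (nx, ny, nz[, channels]); indices are 0-based here, 1-based in R.
#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Linear interpolation, exact at both endpoints and for equal values.
static inline double lerp1(double a, double b, double f) {
  return f <= 0.5 ? a + f * (b - a) : b + (1 - f) * (a - b);
}

// ---------------------------------------------------------------- conv3d

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                            IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], cout = wd[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int ox = (nx + 2 * px - kx) / sx + 1;
  const int oy = (ny + 2 * py - ky) / sy + 1;
  const int oz = (nz + 2 * pz - kz) / sz + 1;
  NumericVector out((R_xlen_t)ox * oy * oz * cout);
  const double *X = x.begin(), *W = w.begin(), *B = b.begin();
  double *O = out.begin();
  for (int co = 0; co < cout; co++) {
    const double bb = B[co];
    for (int ko = 0; ko < oz; ko++)
      for (int jo = 0; jo < oy; jo++)
        for (int io = 0; io < ox; io++) {
          double acc = bb;
          const int bx = io * sx - px, by = jo * sy - py, bz = ko * sz - pz;
          for (int ci = 0; ci < cin; ci++) {
            for (int kzi = 0; kzi < kz; kzi++) {
              const int iz = bz + kzi;
              if (iz < 0 || iz >= nz) continue;
              for (int kyi = 0; kyi < ky; kyi++) {
                const int iy = by + kyi;
                if (iy < 0 || iy >= ny) continue;
                const double *xp =
                    X + (((size_t)ci * nz + iz) * ny + iy) * nx;
                const double *wp =
                    W + ((((size_t)co * cin + ci) * kz + kzi) * ky + kyi) * kx;
                for (int kxi = 0; kxi < kx; kxi++) {
                  const int ix = bx + kxi;
                  if (ix < 0 || ix >= nx) continue;
                  acc += xp[ix] * wp[kxi];
                }
              }
            }
          }
          O[(((size_t)co * oz + ko) * oy + jo) * ox + io] = acc;
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   IntegerVector stride, IntegerVector pad, bool need_gx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], cout = wd[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int ox = yd[0], oy = yd[1], oz = yd[2];
  NumericVector gx(need_gx ? x.size() : 0);
  NumericVector gw(w.size());
  NumericVector gb(cout);
  const double *X = x.begin(), *W = w.begin(), *GY = gy.begin();
  double *GX = gx.begin(), *GW = gw.begin(), *GB = gb.begin();
  for (int co = 0; co < cout; co++) {
    for (int ko = 0; ko < oz; ko++)
      for (int jo = 0; jo < oy; jo++)
        for (int io = 0; io < ox; io++) {
          const double g = GY[(((size_t)co * oz + ko) * oy + jo) * ox + io];
          if (g == 0.0) continue;
          GB[co] += g;
          const int bx = io * sx - px, by = jo * sy - py, bz = ko * sz - pz;
          for (int ci = 0; ci < cin; ci++) {
            for (int kzi = 0; kzi < kz; kzi++) {
              const int iz = bz + kzi;
              if (iz < 0 || iz >= nz) continue;
              for (int kyi = 0; kyi < ky; kyi++) {
                const int iy = by + kyi;
                if (iy < 0 || iy >= ny) continue;
                const size_t xoff = (((size_t)ci * nz + iz) * ny + iy) * nx;
                const size_t woff =
                    ((((size_t)co * cin + ci) * kz + kzi) * ky + kyi) * kx;
                for (int kxi = 0; kxi < kx; kxi++) {
                  const int ix = bx + kxi;
                  if (ix < 0 || ix >= nx) continue;
                  GW[woff + kxi] += g * X[xoff + ix];
                  if (need_gx) GX[xoff + ix] += g * W[woff + kxi];
                }
              }
            }
          }
        }
  }
  if (need_gx) gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ------------------------------------------------------- shifts and sums

// y(v) = x(clamp(v + off)), per-axis clamping to the grid.
// [[Rcpp::export]]
NumericVector cpp_shift3d(NumericVector x, IntegerVector off) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2];
  NumericVector out(x.size());
  const double *X = x.begin();
  double *O = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; k++) {
    const int kk = clampi(k + off[2], 0, nz - 1);
    for (int j = 0; j < ny; j++) {
      const int jj = clampi(j + off[1], 0, ny - 1);
      const double *row = X + ((size_t)kk * ny + jj) * nx;
      for (int i = 0; i < nx; i++, idx++)
        O[idx] = row[clampi(i + off[0], 0, nx - 1)];
    }
  }
  out.attr("dim") = xd;
  return out;
}

// Adjoint of cpp_shift3d: scatter-add g(v) into clamp(v + off).
// [[Rcpp::export]]
NumericVector cpp_shift3d_adj(NumericVector g, IntegerVector off) {
  IntegerVector gd = g.attr("dim");
  const int nx = gd[0], ny = gd[1], nz = gd[2];
  NumericVector out(g.size());
  const double *G = g.begin();
  double *O = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; k++) {
    const int kk = clampi(k + off[2], 0, nz - 1);
    for (int j = 0; j < ny; j++) {
      const int jj = clampi(j + off[1], 0, ny - 1);
      double *row = O + ((size_t)kk * ny + jj) * nx;
      for (int i = 0; i < nx; i++, idx++)
        row[clampi(i + off[0], 0, nx - 1)] += G[idx];
    }
  }
  out.attr("dim") = gd;
  return out;
}

// y(v) = sum over p in [-h, h]^3 of x(clamp(v + p))
// [[Rcpp::export]]
NumericVector cpp_boxsum3d(NumericVector x, IntegerVector half) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2];
  const int hx = half[0], hy = half[1], hz = half[2];
  NumericVector out(x.size());
  const double *X = x.begin();
  double *O = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        double acc = 0.0;
        for (int pz = -hz; pz <= hz; pz++) {
          const int kk = clampi(k + pz, 0, nz - 1);
          for (int py = -hy; py <= hy; py++) {
            const int jj = clampi(j + py, 0, ny - 1);
            const double *row = X + ((size_t)kk * ny + jj) * nx;
            for (int px = -hx; px <= hx; px++)
              acc += row[clampi(i + px, 0, nx - 1)];
          }
        }
        O[idx] = acc;
      }
  out.attr("dim") = xd;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_boxsum3d_adj(NumericVector g, IntegerVector half) {
  IntegerVector gd = g.attr("dim");
  const int nx = gd[0], ny = gd[1], nz = gd[2];
  const int hx = half[0], hy = half[1], hz = half[2];
  NumericVector out(g.size());
  const double *G = g.begin();
  double *O = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        const double gv = G[idx];
        if (gv == 0.0) continue;
        for (int pz = -hz; pz <= hz; pz++) {
          const int kk = clampi(k + pz, 0, nz - 1);
          for (int py = -hy; py <= hy; py++) {
            const int jj = clampi(j + py, 0, ny - 1);
            double *row = O + ((size_t)kk * ny + jj) * nx;
            for (int px = -hx; px <= hx; px++)
              row[clampi(i + px, 0, nx - 1)] += gv;
          }
        }
      }
  out.attr("dim") = gd;
  return out;
}

// ------------------------------------------------------------ upsampling

// Nearest-neighbour upsampling by integer factors per spatial axis.
// [[Rcpp::export]]
NumericVector cpp_upsample_fw(NumericVector x, IntegerVector factor) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  const int fx = factor[0], fy = factor[1], fz = factor[2];
  const int ox = nx * fx, oy = ny * fy, oz = nz * fz;
  NumericVector out((R_xlen_t)ox * oy * oz * nc);
  const double *X = x.begin();
  double *O = out.begin();
  size_t idx = 0;
  for (int c = 0; c < nc; c++)
    for (int k = 0; k < oz; k++)
      for (int j = 0; j < oy; j++) {
        const double *row =
            X + (((size_t)c * nz + k / fz) * ny + j / fy) * nx;
        for (int i = 0; i < ox; i++, idx++) O[idx] = row[i / fx];
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_adj(NumericVector g, IntegerVector factor) {
  IntegerVector gd = g.attr("dim");
  const int ox = gd[0], oy = gd[1], oz = gd[2], nc = gd[3];
  const int fx = factor[0], fy = factor[1], fz = factor[2];
  const int nx = ox / fx, ny = oy / fy, nz = oz / fz;
  NumericVector out((R_xlen_t)nx * ny * nz * nc);
  const double *G = g.begin();
  double *O = out.begin();
  size_t idx = 0;
  for (int c = 0; c < nc; c++)
    for (int k = 0; k < oz; k++)
      for (int j = 0; j < oy; j++) {
        double *row = O + (((size_t)c * nz + k / fz) * ny + j / fy) * nx;
        for (int i = 0; i < ox; i++, idx++) row[i / fx] += G[idx];
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return out;
}

// --------------------------------------------------------------- warping

// out(v) = vol(v + f(v)) with trilinear (or nearest) interpolation and
// clamping of the sample position to the grid.
// [[Rcpp::export]]
NumericVector cpp_warp_fw(NumericVector vol, NumericVector f, bool nearest) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *V = vol.begin(), *F = f.begin();
  double *O = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        double sx = i + F[idx], sy = j + F[idx + nvox],
               sz = k + F[idx + 2 * nvox];
        if (sx < 0) sx = 0; if (sx > nx - 1) sx = nx - 1;
        if (sy < 0) sy = 0; if (sy > ny - 1) sy = ny - 1;
        if (sz < 0) sz = 0; if (sz > nz - 1) sz = nz - 1;
        if (nearest) {
          const int ii = (int)std::lround(sx), jj = (int)std::lround(sy),
                    kk = (int)std::lround(sz);
          O[idx] = V[((size_t)kk * ny + jj) * nx + ii];
        } else {
          const int i0 = nx > 1 ? clampi((int)std::floor(sx), 0, nx - 2) : 0;
          const int j0 = ny > 1 ? clampi((int)std::floor(sy), 0, ny - 2) : 0;
          const int k0 = nz > 1 ? clampi((int)std::floor(sz), 0, nz - 2) : 0;
          const double fxw = sx - i0, fyw = sy - j0, fzw = sz - k0;
          const int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0,
                    k1 = nz > 1 ? k0 + 1 : k0;
          const double c000 = V[((size_t)k0 * ny + j0) * nx + i0];
          const double c100 = V[((size_t)k0 * ny + j0) * nx + i1];
          const double c010 = V[((size_t)k0 * ny + j1) * nx + i0];
          const double c110 = V[((size_t)k0 * ny + j1) * nx + i1];
          const double c001 = V[((size_t)k1 * ny + j0) * nx + i0];
          const double c101 = V[((size_t)k1 * ny + j0) * nx + i1];
          const double c011 = V[((size_t)k1 * ny + j1) * nx + i0];
          const double c111 = V[((size_t)k1 * ny + j1) * nx + i1];
          const double c00 = lerp1(c000, c100, fxw);
          const double c10 = lerp1(c010, c110, fxw);
          const double c01 = lerp1(c001, c101, fxw);
          const double c11 = lerp1(c011, c111, fxw);
          const double c0 = lerp1(c00, c10, fyw);
          const double c1 = lerp1(c01, c11, fyw);
          O[idx] = lerp1(c0, c1, fzw);
        }
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Gradients of cpp_warp_fw (trilinear mode) w.r.t. the volume and the
// displacement field. Clamped samples get zero field gradient.
// [[Rcpp::export]]
List cpp_warp_bw(NumericVector vol, NumericVector f, NumericVector gy,
                 bool need_gv, bool need_gf) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector gv(need_gv ? nvox : 0);
  NumericVector gf(need_gf ? nvox * 3 : 0);
  const double *V = vol.begin(), *F = f.begin(), *GY = gy.begin();
  double *GV = gv.begin(), *GF = gf.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        const double g = GY[idx];
        if (g == 0.0) continue;
        double sx = i + F[idx], sy = j + F[idx + nvox],
               sz = k + F[idx + 2 * nvox];
        const bool cx = (sx < 0 || sx > nx - 1), cy = (sy < 0 || sy > ny - 1),
                   cz = (sz < 0 || sz > nz - 1);
        if (sx < 0) sx = 0; if (sx > nx - 1) sx = nx - 1;
        if (sy < 0) sy = 0; if (sy > ny - 1) sy = ny - 1;
        if (sz < 0) sz = 0; if (sz > nz - 1) sz = nz - 1;
        const int i0 = nx > 1 ? clampi((int)std::floor(sx), 0, nx - 2) : 0;
        const int j0 = ny > 1 ? clampi((int)std::floor(sy), 0, ny - 2) : 0;
        const int k0 = nz > 1 ? clampi((int)std::floor(sz), 0, nz - 2) : 0;
        const double fxw = sx - i0, fyw = sy - j0, fzw = sz - k0;
        const int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0,
                  k1 = nz > 1 ? k0 + 1 : k0;
        const double wx[2] = {1 - fxw, fxw}, wy[2] = {1 - fyw, fyw},
                     wz[2] = {1 - fzw, fzw};
        const int ii[2] = {i0, i1}, jj[2] = {j0, j1}, kk[2] = {k0, k1};
        double dvx = 0, dvy = 0, dvz = 0;
        for (int c = 0; c < 2; c++)
          for (int b = 0; b < 2; b++)
            for (int a = 0; a < 2; a++) {
              const size_t ci = ((size_t)kk[c] * ny + jj[b]) * nx + ii[a];
              const double wgt = wx[a] * wy[b] * wz[c];
              if (need_gv) GV[ci] += g * wgt;
              if (need_gf) {
                const double vv = V[ci];
                dvx += (a == 1 ? 1.0 : -1.0) * wy[b] * wz[c] * vv;
                dvy += wx[a] * (b == 1 ? 1.0 : -1.0) * wz[c] * vv;
                dvz += wx[a] * wy[b] * (c == 1 ? 1.0 : -1.0) * vv;
              }
            }
        if (need_gf) {
          GF[idx] = cx || nx == 1 ? 0.0 : g * dvx;
          GF[idx + nvox] = cy || ny == 1 ? 0.0 : g * dvy;
          GF[idx + 2 * nvox] = cz || nz == 1 ? 0.0 : g * dvz;
        }
      }
  if (need_gv) gv.attr("dim") = vd;
  if (need_gf) gf.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["gv"] = gv, _["gf"] = gf);
}

// Trilinear sampling at arbitrary continuous voxel coordinates
// (0-based), clamped to the grid.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, NumericMatrix coords) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const int m = coords.nrow();
  NumericVector out(m);
  const double *V = vol.begin();
  for (int p = 0; p < m; p++) {
    double sx = coords(p, 0), sy = coords(p, 1), sz = coords(p, 2);
    if (sx < 0) sx = 0; if (sx > nx - 1) sx = nx - 1;
    if (sy < 0) sy = 0; if (sy > ny - 1) sy = ny - 1;
    if (sz < 0) sz = 0; if (sz > nz - 1) sz = nz - 1;
    const int i0 = nx > 1 ? clampi((int)std::floor(sx), 0, nx - 2) : 0;
    const int j0 = ny > 1 ? clampi((int)std::floor(sy), 0, ny - 2) : 0;
    const int k0 = nz > 1 ? clampi((int)std::floor(sz), 0, nz - 2) : 0;
    const double fxw = sx - i0, fyw = sy - j0, fzw = sz - k0;
    const int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0,
              k1 = nz > 1 ? k0 + 1 : k0;
    const double c000 = V[((size_t)k0 * ny + j0) * nx + i0];
    const double c100 = V[((size_t)k0 * ny + j0) * nx + i1];
    const double c010 = V[((size_t)k0 * ny + j1) * nx + i0];
    const double c110 = V[((size_t)k0 * ny + j1) * nx + i1];
    const double c001 = V[((size_t)k1 * ny + j0) * nx + i0];
    const double c101 = V[((size_t)k1 * ny + j0) * nx + i1];
    const double c011 = V[((size_t)k1 * ny + j1) * nx + i0];
    const double c111 = V[((size_t)k1 * ny + j1) * nx + i1];
    const double c00 = lerp1(c000, c100, fxw);
    const double c10 = lerp1(c010, c110, fxw);
    const double c01 = lerp1(c001, c101, fxw);
    const double c11 = lerp1(c011, c111, fxw);
    out[p] = lerp1(lerp1(c00, c10, fyw), lerp1(c01, c11, fyw), fzw);
  }
  return out;
}

// ------------------------------------------------------------ diagnostics

// Fraction of voxels where det(I + grad f) <= 0; central differences on
// interior voxels, one-sided at axes of length 2, axes of length 1
// contribute an identity row.
// [[Rcpp::export]]
double cpp_fold_fraction(NumericVector f) {
  IntegerVector fd = f.attr("dim");
  const int nx = fd[0], ny = fd[1], nz = fd[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const double *F = f.begin();
  const int ilo = nx >= 3 ? 1 : 0, ihi = nx >= 3 ? nx - 2 : nx - 1;
  const int jlo = ny >= 3 ? 1 : 0, jhi = ny >= 3 ? ny - 2 : ny - 1;
  const int klo = nz >= 3 ? 1 : 0, khi = nz >= 3 ? nz - 2 : nz - 1;
  size_t total = 0, folded = 0;
  for (int k = klo; k <= khi; k++)
    for (int j = jlo; j <= jhi; j++)
      for (int i = ilo; i <= ihi; i++) {
        double J[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        for (int c = 0; c < 3; c++) {
          const double *Fc = F + (size_t)c * nvox;
          // d f_c / d x
          if (nx >= 3)
            J[c][0] += 0.5 * (Fc[((size_t)k * ny + j) * nx + i + 1] -
                              Fc[((size_t)k * ny + j) * nx + i - 1]);
          else if (nx == 2)
            J[c][0] += Fc[((size_t)k * ny + j) * nx + 1] -
                       Fc[((size_t)k * ny + j) * nx + 0];
          if (ny >= 3)
            J[c][1] += 0.5 * (Fc[((size_t)k * ny + j + 1) * nx + i] -
                              Fc[((size_t)k * ny + j - 1) * nx + i]);
          else if (ny == 2)
            J[c][1] += Fc[((size_t)k * ny + 1) * nx + i] -
                       Fc[((size_t)k * ny + 0) * nx + i];
          if (nz >= 3)
            J[c][2] += 0.5 * (Fc[((size_t)(k + 1) * ny + j) * nx + i] -
                              Fc[((size_t)(k - 1) * ny + j) * nx + i]);
          else if (nz == 2)
            J[c][2] += Fc[((size_t)1 * ny + j) * nx + i] -
                       Fc[((size_t)0 * ny + j) * nx + i];
        }
        const double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                           J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                           J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        total++;
        if (det <= 0.0) folded++;
      }
  return total == 0 ? 0.0 : (double)folded / (double)total;
}

// ----------------------------------------------- distance transforms / ASD

static void dt1d(const double *fin, double *dout, int *v, double *z, int n,
                 double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -DBL_MAX;
  z[1] = DBL_MAX;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((fin[q] + w2 * q * q) - (fin[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    const double d = (double)(q - v[k]);
    dout[q] = w2 * d * d + fin[v[k]];
  }
}

// Squared Euclidean distance (mm^2, anisotropic spacing) to the nearest
// TRUE voxel; Felzenszwalb-Huttenlocher separable transform.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector d(nvox);
  for (size_t i = 0; i < nvox; i++) d[i] = mask[i] ? 0.0 : DBL_MAX / 4;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> buf(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x axis
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      double *row = d.begin() + ((size_t)k * ny + j) * nx;
      if (nx == 1) continue;
      dt1d(row, out.data(), v.data(), z.data(), nx, w2);
      std::copy(out.begin(), out.begin() + nx, row);
    }
  // y axis
  w2 = spacing[1] * spacing[1];
  if (ny > 1)
    for (int k = 0; k < nz; k++)
      for (int i = 0; i < nx; i++) {
        for (int j = 0; j < ny; j++)
          buf[j] = d[((size_t)k * ny + j) * nx + i];
        dt1d(buf.data(), out.data(), v.data(), z.data(), ny, w2);
        for (int j = 0; j < ny; j++)
          d[((size_t)k * ny + j) * nx + i] = out[j];
      }
  // z axis
  w2 = spacing[2] * spacing[2];
  if (nz > 1)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        for (int k = 0; k < nz; k++)
          buf[k] = d[((size_t)k * ny + j) * nx + i];
        dt1d(buf.data(), out.data(), v.data(), z.data(), nz, w2);
        for (int k = 0; k < nz; k++)
          d[((size_t)k * ny + j) * nx + i] = out[k];
      }
  d.attr("dim") = dims;
  return d;
}

// For each row of A (0-based voxel indices), the minimum Euclidean
// distance in mm to any row of B under the given spacing.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b,
                            NumericVector spacing) {
  const int m = a.nrow(), n = b.nrow();
  NumericVector out(m);
  const double s0 = spacing[0], s1 = spacing[1], s2 = spacing[2];
  for (int i = 0; i < m; i++) {
    double best = DBL_MAX;
    const double a0 = a(i, 0) * s0, a1 = a(i, 1) * s1, a2 = a(i, 2) * s2;
    for (int j = 0; j < n; j++) {
      const double d0 = a0 - b(j, 0) * s0, d1 = a1 - b(j, 1) * s1,
                   d2 = a2 - b(j, 2) * s2;
      const double dd = d0 * d0 + d1 * d1 + d2 * d2;
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
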