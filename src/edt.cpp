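#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Voxel linear order matches R arrays with dim = (nz, ny, nx):
// i = iz + nz * (iy + ny * ix), 0-based, z fastest.

static const double DT_INF = 1e30;

// 1D squared-distance lower-envelope transform (Felzenszwalb & Huttenlocher)
// over samples at coordinates q * w, q = 0..n-1.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double uq = q * w;
    double s;
    while (true) {
      int p = v[k];
      double up = p * w;
      s = ((f[q] + uq * uq) - (f[p] + up * up)) / (2.0 * (uq - up));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double uq = q * w;
    while (z[k + 1] < uq) ++k;
    double du = uq - v[k] * w;
    d[q] = du * du + f[v[k]];
  }
}

// Exact squared Euclidean distance of every voxel to the nearest background
// (fg == 0) voxel, with optional anisotropic spacing (sz, sy, sx).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector fg, int nz, int ny, int nx,
                         double sz, double sy, double sx) {
  R_xlen_t N = (R_xlen_t)nz * ny * nx;
  NumericVector d(N);
  for (R_xlen_t i = 0; i < N; ++i) d[i] = fg[i] ? DT_INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> fbuf(nmax), dbuf(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
      for (int iz = 0; iz < nz; ++iz) fbuf[iz] = d[base + iz];
      dt1d(fbuf.data(), dbuf.data(), nz, sz, v, z);
      for (int iz = 0; iz < nz; ++iz) d[base + iz] = dbuf[iz];
    }
  // pass along y (stride nz)
  for (int ix = 0; ix < nx; ++ix)
    for (int iz = 0; iz < nz; ++iz) {
      R_xlen_t base = iz + (R_xlen_t)nz * ny * ix;
      for (int iy = 0; iy < ny; ++iy) fbuf[iy] = d[base + (R_xlen_t)nz * iy];
      dt1d(fbuf.data(), dbuf.data(), ny, sy, v, z);
      for (int iy = 0; iy < ny; ++iy) d[base + (R_xlen_t)nz * iy] = dbuf[iy];
    }
  // pass along x (stride nz*ny)
  R_xlen_t sxstride = (R_xlen_t)nz * ny;
  for (int iy = 0; iy < ny; ++iy)
    for (int iz = 0; iz < nz; ++iz) {
      R_xlen_t base = iz + (R_xlen_t)nz * iy;
      for (int ix = 0; ix < nx; ++ix) fbuf[ix] = d[base + sxstride * ix];
      dt1d(fbuf.data(), dbuf.data(), nx, sx, v, z);
      for (int ix = 0; ix < nx; ++ix) d[base + sxstride * ix] = dbuf[ix];
    }
  return d;
}

// Displacement (in voxel index units) of each foreground voxel to its nearest
// background voxel, given the exact squared distances.  Ties are broken by the
// smallest (z, y, x) lexicographic coordinate of the background voxel, i.e.
// the smallest linear index in z-major order.
// [[Rcpp::export]]
List cpp_dvf(IntegerVector fg, NumericVector dsq, int nz, int ny, int nx,
             double sz, double sy, double sx) {
  R_xlen_t N = (R_xlen_t)nz * ny * nx;
  NumericVector dx(N), dy(N), dz(N);
  bool iso = (sz == 1.0 && sy == 1.0 && sx == 1.0);
  const double eps = 1e-6;

  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        R_xlen_t i = iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
        if (!fg[i]) { dx[i] = dy[i] = dz[i] = 0.0; continue; }
        double D = dsq[i];
        bool found = false;
        int rz = (int)std::floor(std::sqrt(D) / sz + 1e-9);
        for (int zz = std::max(0, iz - rz); zz <= std::min(nz - 1, iz + rz) && !found; ++zz) {
          double remz = D - (double)(zz - iz) * (zz - iz) * sz * sz;
          if (remz < -eps) continue;
          if (remz < 0) remz = 0;
          int ry = (int)std::floor(std::sqrt(remz) / sy + 1e-9);
          for (int yy = std::max(0, iy - ry); yy <= std::min(ny - 1, iy + ry) && !found; ++yy) {
            double remy = remz - (double)(yy - iy) * (yy - iy) * sy * sy;
            if (remy < -eps) continue;
            if (remy < 0) remy = 0;
            if (iso) {
              // remy must be a perfect square for a candidate to exist
              long long s = (long long)std::llround(std::sqrt(remy));
              if ((double)(s * s) != std::floor(remy + 0.5)) continue;
              int cand[2] = { ix - (int)s, ix + (int)s };
              int ncand = (s == 0) ? 1 : 2;
              for (int c = 0; c < ncand && !found; ++c) {
                int xx = cand[c];
                if (xx < 0 || xx >= nx) continue;
                R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
                if (!fg[j]) {
                  dx[i] = ix - xx; dy[i] = iy - yy; dz[i] = iz - zz;
                  found = true;
                }
              }
            } else {
              int rx = (int)std::floor(std::sqrt(remy) / sx + 1e-9) + 1;
              for (int xx = std::max(0, ix - rx); xx <= std::min(nx - 1, ix + rx) && !found; ++xx) {
                double dd = remy - (double)(xx - ix) * (xx - ix) * sx * sx;
                if (std::fabs(dd) > eps * (1.0 + D)) continue;
                R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
                if (!fg[j]) {
                  dx[i] = ix - xx; dy[i] = iy - yy; dz[i] = iz - zz;
                  found = true;
                }
              }
            }
          }
        }
        if (!found) stop("internal error: no background voxel at the EDT distance");
      }
  return List::create(_["dx"] = dx, _["dy"] = dy, _["dz"] = dz);
}
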