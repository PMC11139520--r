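#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature maps are (C x N) matrices over voxels in R array linear order,
// i = iz + nz * (iy + ny * ix).  3x3x3 kernels, zero padding 1, stride 1.
// Kernel offsets are enumerated kx, ky, kz each in -1..1 (kz fastest); the
// weight matrix is (C_out x C_in*27) with one C_in-row block per offset.

// Padded-volume GEMM convolution: the volume is copied once into a zero-
// padded buffer whose linear layout makes every kernel offset a constant
// column shift, so each of the 27 taps is one contiguous-view GEMM.  No
// im2col matrix is ever materialised.

static arma::mat pad_volume(const arma::mat& x, int nz, int ny, int nx) {
  const int C = x.n_rows;
  const int pz = nz + 2, py = ny + 2, px = nx + 2;
  arma::mat xp(C, (arma::uword)pz * py * px, arma::fill::zeros);
  const double* s = x.memptr();
  double* d = xp.memptr();
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      arma::uword n = (arma::uword)nz * (iy + (arma::uword)ny * ix);
      arma::uword p = 1 + (arma::uword)pz * ((iy + 1) + (arma::uword)py * (ix + 1));
      std::memcpy(d + p * C, s + n * C, (size_t)nz * C * sizeof(double));
    }
  return xp;
}

static arma::mat crop_volume(const arma::mat& xp, int C, int nz, int ny, int nx) {
  const int pz = nz + 2, py = ny + 2;
  arma::mat x(C, (arma::uword)nz * ny * nx, arma::fill::none);
  const double* s = xp.memptr();
  double* d = x.memptr();
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      arma::uword n = (arma::uword)nz * (iy + (arma::uword)ny * ix);
      arma::uword p = 1 + (arma::uword)pz * ((iy + 1) + (arma::uword)py * (ix + 1));
      std::memcpy(d + n * C, s + p * C, (size_t)nz * C * sizeof(double));
    }
  return x;
}

// non-owning contiguous column-range view
static inline arma::mat colview(const arma::mat& m, arma::uword first,
                                arma::uword len) {
  return arma::mat(const_cast<double*>(m.memptr()) + first * m.n_rows,
                   m.n_rows, len, false, true);
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_forward(const arma::mat& x, const arma::mat& W,
                             const arma::vec& b, int nz, int ny, int nx) {
  const int Cin = x.n_rows, Cout = W.n_rows;
  const int pz = nz + 2, py = ny + 2, px = nx + 2;
  const arma::uword Np = (arma::uword)pz * py * px;
  arma::mat xp = pad_volume(x, nz, ny, nx);
  arma::mat op(Cout, Np, arma::fill::zeros);
  int o = 0;
  for (int kx = -1; kx <= 1; ++kx)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kz = -1; kz <= 1; ++kz, ++o) {
        long long so = kz + (long long)pz * (ky + (long long)py * kx);
        arma::uword a = (arma::uword)std::max(0LL, -so);
        arma::uword len = Np - std::llabs(so);
        arma::mat Wo(const_cast<double*>(W.memptr()) +
                       (arma::uword)o * Cout * Cin,
                     Cout, Cin, false, true);
        colview(op, a, len) += Wo * colview(xp, a + so, len);
      }
  arma::mat out = crop_volume(op, Cout, nz, ny, nx);
  out.each_col() += b;
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(const arma::mat& x, const arma::mat& W,
                         const arma::mat& gout, int nz, int ny, int nx) {
  const int Cin = x.n_rows, Cout = W.n_rows;
  const int pz = nz + 2, py = ny + 2, px = nx + 2;
  const arma::uword Np = (arma::uword)pz * py * px;
  arma::mat xp = pad_volume(x, nz, ny, nx);
  arma::mat gp = pad_volume(gout, nz, ny, nx);
  arma::mat ginp(Cin, Np, arma::fill::zeros);
  arma::mat gW(Cout, (arma::uword)27 * Cin, arma::fill::none);
  int o = 0;
  for (int kx = -1; kx <= 1; ++kx)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kz = -1; kz <= 1; ++kz, ++o) {
        long long so = kz + (long long)pz * (ky + (long long)py * kx);
        arma::uword a = (arma::uword)std::max(0LL, -so);
        arma::uword len = Np - std::llabs(so);
        arma::mat Wo(const_cast<double*>(W.memptr()) +
                       (arma::uword)o * Cout * Cin,
                     Cout, Cin, false, true);
        arma::mat gWo(gW.memptr() + (arma::uword)o * Cout * Cin,
                      Cout, Cin, false, true);
        // out(p) += Wo * x(p + so)  =>  gW_o = sum_p g(p) x(p+so)^T
        gWo = colview(gp, a, len) * colview(xp, a + so, len).t();
        // dL/dx(p+so) += Wo^T g(p)
        colview(ginp, a + so, len) += Wo.t() * colview(gp, a, len);
      }
  arma::mat gin = crop_volume(ginp, Cin, nz, ny, nx);
  arma::vec gb = arma::sum(gout, 1);
  return List::create(_["gin"] = gin, _["gW"] = gW, _["gb"] = gb);
}

// 2x2x2 max pooling; dims must be even.  Returns pooled map and, per channel,
// the 1-based input column index of each maximum (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& x, int nz, int ny, int nx) {
  int C = x.n_rows;
  int oz = nz / 2, oy = ny / 2, ox = nx / 2;
  arma::uword No = (arma::uword)oz * oy * ox;
  arma::mat out(C, No);
  arma::umat idx(C, No);
  for (int px = 0; px < ox; ++px)
    for (int py = 0; py < oy; ++py)
      for (int pz = 0; pz < oz; ++pz) {
        arma::uword n = pz + (arma::uword)oz * (py + (arma::uword)oy * px);
        for (int c = 0; c < C; ++c) {
          double best = -arma::datum::inf;
          arma::uword besti = 0;
          for (int dxk = 0; dxk < 2; ++dxk)
            for (int dyk = 0; dyk < 2; ++dyk)
              for (int dzk = 0; dzk < 2; ++dzk) {
                arma::uword j = (2 * pz + dzk) +
                  (arma::uword)nz * ((2 * py + dyk) + (arma::uword)ny * (2 * px + dxk));
                double v = x(c, j);
                if (v > best) { best = v; besti = j; }
              }
          out(c, n) = best;
          idx(c, n) = besti + 1;  // 1-based for R
        }
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& gout, const arma::umat& idx,
                          int Nin) {
  int C = gout.n_rows;
  arma::mat gin(C, Nin, arma::fill::zeros);
  for (arma::uword n = 0; n < gout.n_cols; ++n)
    for (int c = 0; c < C; ++c)
      gin(c, idx(c, n) - 1) += gout(c, n);
  return gin;
}
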