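// Compiled numerical kernels: zero-padded 3x3x3 convolution (forward and
// backward passes, im2col + BLAS, chunked along z to bound memory) and the
// exact anisotropic squared-Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope algorithm, separable per axis).
//
// Feature maps are stored as nvox x C matrices; voxel v = x + nx*(y + ny*z)
// (0-based, x fastest). Convolution weights are (27*Cin) x Cout with row
// index r = k + 27*c for tap k = (dx+1) + 3*(dy+1) + 9*(dz+1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col_chunk(const arma::mat& X, int nx, int ny, int nz,
                                int z0, int z1, arma::mat& P) {
  const int Cin = X.n_cols;
  const int nxy = nx * ny;
  P.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int k = 0; k < 27; ++k) {
      const int dx = k % 3 - 1, dy = (k / 3) % 3 - 1, dz = k / 9 - 1;
      double* pc = P.colptr(c * 27 + k);
      const int x_lo = std::max(0, -dx), x_hi = std::min(nx, nx - dx);
      if (x_hi <= x_lo) continue;
      for (int z = z0; z < z1; ++z) {
        const int sz = z + dz;
        if (sz < 0 || sz >= nz) continue;
        for (int y = 0; y < ny; ++y) {
          const int sy = y + dy;
          if (sy < 0 || sy >= ny) continue;
          const double* src = xc + (x_lo + dx) + nx * (sy + (std::size_t)ny * sz);
          double* dst = pc + x_lo + nx * (y + (std::size_t)ny * (z - z0));
          std::memcpy(dst, src, (x_hi - x_lo) * sizeof(double));
        }
      }
    }
  }
}

static inline int chunk_slices(int nx, int ny, int Cin) {
  double rows_budget = 6.0e6 / std::max(1, 27 * Cin);
  int zc = (int)std::floor(rows_budget / std::max(1, nx * ny));
  return std::max(1, zc);
}

// [[Rcpp::export(name = ".conv3_forward")]]
arma::mat conv3_forward(const arma::mat& X, IntegerVector dims,
                        const arma::mat& W, const arma::rowvec& bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.n_cols, Cout = W.n_cols;
  if ((int)W.n_rows != 27 * Cin) stop("weight/input channel mismatch");
  arma::mat Y((std::size_t)nx * ny * nz, Cout);
  const int zc = chunk_slices(nx, ny, Cin);
  arma::mat P;
  for (int z0 = 0; z0 < nz; z0 += zc) {
    const int z1 = std::min(nz, z0 + zc);
    const std::size_t r0 = (std::size_t)nx * ny * z0;
    const std::size_t nrow = (std::size_t)nx * ny * (z1 - z0);
    P.set_size(nrow, 27 * Cin);
    im2col_chunk(X, nx, ny, nz, z0, z1, P);
    arma::mat Yc = P * W;
    Yc.each_row() += bias;
    Y.rows(r0, r0 + nrow - 1) = Yc;
  }
  return Y;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(const arma::mat& X, IntegerVector dims, const arma::mat& W,
                    const arma::mat& GY) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = X.n_cols, Cout = W.n_cols;
  const int nxy = nx * ny;
  arma::mat GW(27 * Cin, Cout, arma::fill::zeros);
  arma::rowvec gb = arma::sum(GY, 0);
  arma::mat GX(X.n_rows, Cin, arma::fill::zeros);
  const int zc = chunk_slices(nx, ny, Cin);
  arma::mat P;
  for (int z0 = 0; z0 < nz; z0 += zc) {
    const int z1 = std::min(nz, z0 + zc);
    const std::size_t r0 = (std::size_t)nxy * z0;
    const std::size_t nrow = (std::size_t)nxy * (z1 - z0);
    P.set_size(nrow, 27 * Cin);
    im2col_chunk(X, nx, ny, nz, z0, z1, P);
    const arma::mat GYc = GY.rows(r0, r0 + nrow - 1);
    GW += P.t() * GYc;
    arma::mat GP = GYc * W.t();  // nrow x 27*Cin
    // scatter-add (col2im): GX[x+dx, y+dy, z+dz, c] += GP[v_local, c*27+k]
    for (int c = 0; c < Cin; ++c) {
      double* gxc = GX.colptr(c);
      for (int k = 0; k < 27; ++k) {
        const int dx = k % 3 - 1, dy = (k / 3) % 3 - 1, dz = k / 9 - 1;
        const double* gp = GP.colptr(c * 27 + k);
        const int x_lo = std::max(0, -dx), x_hi = std::min(nx, nx - dx);
        if (x_hi <= x_lo) continue;
        for (int z = z0; z < z1; ++z) {
          const int sz = z + dz;
          if (sz < 0 || sz >= nz) continue;
          for (int y = 0; y < ny; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= ny) continue;
            double* dst = gxc + (x_lo + dx) + nx * (sy + (std::size_t)ny * sz);
            const double* src = gp + x_lo + nx * (y + (std::size_t)ny * (z - z0));
            for (int x = 0; x < x_hi - x_lo; ++x) dst[x] += src[x];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = GX, _["gw"] = GW, _["gb"] = gb);
}

// 1D squared-distance transform along a strided line (lower envelope).
static void dt1d(const double* f, double* d, int n, double s2, int* v,
                 double* z, double* fbuf) {
  for (int i = 0; i < n; ++i) fbuf[i] = f[i];
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    if (!std::isfinite(fbuf[q]) && !std::isfinite(fbuf[v[k]])) { continue; }
    double sden = 2.0 * s2 * (q - v[k]);
    double sc = ((fbuf[q] + s2 * q * q) - (fbuf[v[k]] + s2 * v[k] * v[k])) / sden;
    while (k > 0 && sc <= z[k]) {
      --k;
      sden = 2.0 * s2 * (q - v[k]);
      sc = ((fbuf[q] + s2 * q * q) - (fbuf[v[k]] + s2 * v[k] * v[k])) / sden;
    }
    ++k;
    v[k] = q;
    z[k] = sc;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + fbuf[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3")]]
NumericVector edt3(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::size_t nvox = (std::size_t)nx * ny * nz;
  std::vector<double> d(nvox);
  for (std::size_t i = 0; i < nvox; ++i) d[i] = mask[i] ? 0.0 : INFINITY;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), out(nmax), z(nmax + 1), fbuf(nmax);
  std::vector<int> v(nmax);
  // along x
  double s2 = spacing[0] * spacing[0];
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      double* p = &d[(std::size_t)nx * (y + (std::size_t)ny * zz)];
      dt1d(p, out.data(), nx, s2, v.data(), z.data(), fbuf.data());
      std::memcpy(p, out.data(), nx * sizeof(double));
    }
  // along y
  s2 = spacing[1] * spacing[1];
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = d[x + nx * (y + (std::size_t)ny * zz)];
      dt1d(line.data(), out.data(), ny, s2, v.data(), z.data(), fbuf.data());
      for (int y = 0; y < ny; ++y) d[x + nx * (y + (std::size_t)ny * zz)] = out[y];
    }
  // along z
  s2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int zz = 0; zz < nz; ++zz) line[zz] = d[x + nx * (y + (std::size_t)ny * zz)];
      dt1d(line.data(), out.data(), nz, s2, v.data(), z.data(), fbuf.data());
      for (int zz = 0; zz < nz; ++zz) d[x + nx * (y + (std::size_t)ny * zz)] = out[zz];
    }
  NumericVector res(nvox);
  for (std::size_t i = 0; i < nvox; ++i) res[i] = std::sqrt(d[i]);
  res.attr("dim") = dims;
  return res;
}
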