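#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Parallel-beam, single-axis projector about the y (second) grid axis.
//
// Volume: (nx, ny, nz) column-major, voxel centre i at continuous coord i.
// Sinogram: (ndet, ny, nangles); detector bin u centred at u - (ndet-1)/2
// relative to the in-plane grid centre.
//
// Rays live in the x-z plane of each y slice: at tilt angle a (radians,
// 0 = viewing along +z) the ray direction is (sin a, cos a) and the detector
// axis is (cos a, -sin a). Samples are taken at unit (voxel) steps along the
// ray with bilinear interpolation; the backprojector scatters with the
// identical weights, so the pair is an exact adjoint up to float rounding.
//
// Because the ray geometry is the same in every slice, the volume is held
// internally in y-fastest order and each bilinear sample is applied to all
// ny slices at once as four contiguous streams; this keeps the hot loop
// vectorizable and cache-linear.
//
// Line integrals are returned in voxel units; physical scaling (voxel size)
// is applied by the R wrappers.

static inline void ray_range(double ox, double oz, double dx, double dz,
                             double xmin, double xmax, double zmin, double zmax,
                             double &t0, double &t1) {
  t0 = -1e30;
  t1 = 1e30;
  if (std::fabs(dx) > 1e-12) {
    double a = (xmin - ox) / dx, b = (xmax - ox) / dx;
    if (a > b) std::swap(a, b);
    if (a > t0) t0 = a;
    if (b < t1) t1 = b;
  } else if (ox < xmin || ox > xmax) {
    t0 = 1.0; t1 = 0.0; return;
  }
  if (std::fabs(dz) > 1e-12) {
    double a = (zmin - oz) / dz, b = (zmax - oz) / dz;
    if (a > b) std::swap(a, b);
    if (a > t0) t0 = a;
    if (b < t1) t1 = b;
  } else if (oz < zmin || oz > zmax) {
    t0 = 1.0; t1 = 0.0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector vdim,
                                  NumericVector angles_rad, int ndet,
                                  double step) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int na = angles_rad.size();
  NumericVector sino(static_cast<R_xlen_t>(ndet) * ny * na);
  const int px = nx + 2, pz = nz + 2;  // zero padding of 1 voxel on x and z
  // y-fastest padded copy: V[iy + ny*((ix+1) + px*(iz+1))]
  std::vector<double> V(static_cast<size_t>(ny) * px * pz, 0.0);
  const double *v = REAL(vol);
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      double *dst = &V[static_cast<size_t>(ny) * ((ix + 1) + static_cast<size_t>(px) * (iz + 1))];
      const double *src = v + ix + static_cast<size_t>(nx) * ny * iz;
      for (int iy = 0; iy < ny; ++iy) dst[iy] = src[static_cast<size_t>(nx) * iy];
    }
  const double cx = 0.5 * (nx - 1), cz = 0.5 * (nz - 1), cu = 0.5 * (ndet - 1);
  const double xmin = -0.5, xmax = nx - 0.5, zmin = -0.5, zmax = nz - 0.5;
  std::vector<double> acc(ny);
  double *s = REAL(sino);
  for (int a = 0; a < na; ++a) {
    const double dx = std::sin(angles_rad[a]), dz = std::cos(angles_rad[a]);
    const double ex = dz, ez = -dx;
    for (int u = 0; u < ndet; ++u) {
      const double off = u - cu;
      const double ox = cx + off * ex, oz = cz + off * ez;
      double t0, t1;
      ray_range(ox, oz, dx, dz, xmin, xmax, zmin, zmax, t0, t1);
      std::fill(acc.begin(), acc.end(), 0.0);
      if (t1 > t0) {
        const int K = static_cast<int>((t1 - t0) / step + 0.5);
        double x = ox + (t0 + 0.5 * step) * dx + 1.0;  // +1: pad offset
        double z = oz + (t0 + 0.5 * step) * dz + 1.0;
        const double ddx = dx * step, ddz = dz * step;
        double *ac = acc.data();
        for (int k = 0; k < K; ++k) {
          const int ix0 = static_cast<int>(x), iz0 = static_cast<int>(z);
          const double fx = x - ix0, fz = z - iz0;
          const double w00 = (1.0 - fx) * (1.0 - fz), w10 = fx * (1.0 - fz);
          const double w01 = (1.0 - fx) * fz, w11 = fx * fz;
          const double *p00 = &V[static_cast<size_t>(ny) * (ix0 + static_cast<size_t>(px) * iz0)];
          const double *p10 = p00 + ny;
          const double *p01 = p00 + static_cast<size_t>(ny) * px;
          const double *p11 = p01 + ny;
          for (int iy = 0; iy < ny; ++iy)
            ac[iy] += w00 * p00[iy] + w10 * p10[iy] + w01 * p01[iy] + w11 * p11[iy];
          x += ddx;
          z += ddz;
        }
      }
      for (int iy = 0; iy < ny; ++iy)
        s[u + static_cast<size_t>(ndet) * (iy + static_cast<size_t>(ny) * a)] = acc[iy] * step;
    }
  }
  sino.attr("dim") = IntegerVector::create(ndet, ny, na);
  return sino;
}

// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector sino, IntegerVector sdim,
                               IntegerVector vdim, NumericVector angles_rad,
                               double step) {
  const int ndet = sdim[0], ny = sdim[1], na = sdim[2];
  const int nx = vdim[0], nz = vdim[2];
  if (vdim[1] != ny) stop("slice count mismatch between sinogram and volume");
  if (na != angles_rad.size()) stop("angle count mismatch");
  NumericVector vol(static_cast<R_xlen_t>(nx) * ny * nz);
  const int px = nx + 2, pz = nz + 2;
  std::vector<double> V(static_cast<size_t>(ny) * px * pz, 0.0);
  const double cx = 0.5 * (nx - 1), cz = 0.5 * (nz - 1), cu = 0.5 * (ndet - 1);
  const double xmin = -0.5, xmax = nx - 0.5, zmin = -0.5, zmax = nz - 0.5;
  std::vector<double> w(ny);
  const double *s = REAL(sino);
  for (int a = 0; a < na; ++a) {
    const double dx = std::sin(angles_rad[a]), dz = std::cos(angles_rad[a]);
    const double ex = dz, ez = -dx;
    for (int u = 0; u < ndet; ++u) {
      const double off = u - cu;
      const double ox = cx + off * ex, oz = cz + off * ez;
      double t0, t1;
      ray_range(ox, oz, dx, dz, xmin, xmax, zmin, zmax, t0, t1);
      if (t1 <= t0) continue;
      for (int iy = 0; iy < ny; ++iy)
        w[iy] = s[u + static_cast<size_t>(ndet) * (iy + static_cast<size_t>(ny) * a)] * step;
      const int K = static_cast<int>((t1 - t0) / step + 0.5);
      double x = ox + (t0 + 0.5 * step) * dx + 1.0;
      double z = oz + (t0 + 0.5 * step) * dz + 1.0;
      const double ddx = dx * step, ddz = dz * step;
      const double *wc = w.data();
      for (int k = 0; k < K; ++k) {
        const int ix0 = static_cast<int>(x), iz0 = static_cast<int>(z);
        const double fx = x - ix0, fz = z - iz0;
        const double w00 = (1.0 - fx) * (1.0 - fz), w10 = fx * (1.0 - fz);
        const double w01 = (1.0 - fx) * fz, w11 = fx * fz;
        double *p00 = &V[static_cast<size_t>(ny) * (ix0 + static_cast<size_t>(px) * iz0)];
        double *p10 = p00 + ny;
        double *p01 = p00 + static_cast<size_t>(ny) * px;
        double *p11 = p01 + ny;
        for (int iy = 0; iy < ny; ++iy) {
          const double wy = wc[iy];
          p00[iy] += w00 * wy;
          p10[iy] += w10 * wy;
          p01[iy] += w01 * wy;
          p11[iy] += w11 * wy;
        }
        x += ddx;
        z += ddz;
      }
    }
  }
  double *out = REAL(vol);
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      const double *src = &V[static_cast<size_t>(ny) * ((ix + 1) + static_cast<size_t>(px) * (iz + 1))];
      double *dst = out + ix + static_cast<size_t>(nx) * ny * iz;
      for (int iy = 0; iy < ny; ++iy) dst[static_cast<size_t>(nx) * iy] = src[iy];
    }
  vol.attr("dim") = vdim;
  return vol;
}
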