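#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian-atom density synthesis and statistical-geometry energy kernels.
// Grids are 0-based, x-fastest (R array order, dim = c(nx, ny, nz)); voxel
// centre i maps to origin + i * spacing. All angles are in degrees.

static inline int vidx(int ix, int iy, int iz, int nx, int ny) {
  return ix + nx * (iy + ny * iz);
}

// [[Rcpp::export]]
NumericVector cpp_density(NumericMatrix pos, NumericVector amp,
                          NumericVector sig2, NumericVector origin,
                          double spacing, IntegerVector dims, double cutoff) {
  const int n = pos.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(nx * ny * nz);
  const double cut2 = cutoff * cutoff;
  for (int a = 0; a < n; ++a) {
    const double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    const double s2 = sig2[a], A = amp[a];
    int lo[3], hi[3];
    const double p[3] = { px, py, pz };
    for (int d = 0; d < 3; ++d) {
      lo[d] = (int)std::ceil((p[d] - cutoff - origin[d]) / spacing);
      hi[d] = (int)std::floor((p[d] + cutoff - origin[d]) / spacing);
      if (lo[d] < 0) lo[d] = 0;
      const int dmax = dims[d] - 1;
      if (hi[d] > dmax) hi[d] = dmax;
    }
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      const double dz = origin[2] + iz * spacing - pz;
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        const double dy = origin[1] + iy * spacing - py;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > cut2) continue;
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          const double dx = origin[0] + ix * spacing - px;
          const double r2 = dx * dx + dyz2;
          if (r2 > cut2) continue;
          out[vidx(ix, iy, iz, nx, ny)] += A * std::exp(-r2 / (2.0 * s2));
        }
      }
    }
  }
  return out;
}

// Gradient of pref * sum(diff^2) w.r.t. atom positions, where
// diff = model_density - target and pref folds all scaling.
// [[Rcpp::export]]
NumericMatrix cpp_density_grad(NumericMatrix pos, NumericVector amp,
                               NumericVector sig2, NumericVector origin,
                               double spacing, IntegerVector dims,
                               NumericVector diff, double cutoff,
                               double pref) {
  const int n = pos.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix grad(n, 3);
  const double cut2 = cutoff * cutoff;
  for (int a = 0; a < n; ++a) {
    const double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    const double s2 = sig2[a], A = amp[a];
    const double p[3] = { px, py, pz };
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = (int)std::ceil((p[d] - cutoff - origin[d]) / spacing);
      hi[d] = (int)std::floor((p[d] + cutoff - origin[d]) / spacing);
      if (lo[d] < 0) lo[d] = 0;
      const int dmax = dims[d] - 1;
      if (hi[d] > dmax) hi[d] = dmax;
    }
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      const double dz = origin[2] + iz * spacing - pz;
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        const double dy = origin[1] + iy * spacing - py;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > cut2) continue;
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          const double dx = origin[0] + ix * spacing - px;
          const double r2 = dx * dx + dyz2;
          if (r2 > cut2) continue;
          const double rho = A * std::exp(-r2 / (2.0 * s2));
          // d(rho)/d(p) = rho * (x_v - p)/s2 ; dE/dp = pref*2*diff*drho/dp
          const double w = pref * 2.0 * diff[vidx(ix, iy, iz, nx, ny)] *
            rho / s2;
          gx += w * dx;
          gy += w * dy;
          gz += w * dz;
        }
      }
    }
    grad(a, 0) = gx;
    grad(a, 1) = gy;
    grad(a, 2) = gz;
  }
  return grad;
}

// Bond terms: E_t = ((r - v0)/sigma)^2. Returns signed deviates and the
// gradient of sum(E) accumulated per atom.
// [[Rcpp::export]]
List cpp_bond_terms(NumericMatrix pos, IntegerMatrix idx, NumericVector v0,
                    NumericVector sigma, bool want_grad) {
  const int n = idx.nrow();
  const int natom = pos.nrow();
  NumericVector dev(n);
  NumericMatrix grad(want_grad ? natom : 1, 3);
  for (int t = 0; t < n; ++t) {
    const int i = idx(t, 0) - 1, j = idx(t, 1) - 1;
    const double dx = pos(i, 0) - pos(j, 0);
    const double dy = pos(i, 1) - pos(j, 1);
    const double dz = pos(i, 2) - pos(j, 2);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double d = (r - v0[t]) / sigma[t];
    dev[t] = d;
    if (want_grad && r > 1e-10) {
      const double w = 2.0 * d / (sigma[t] * r);
      grad(i, 0) += w * dx; grad(i, 1) += w * dy; grad(i, 2) += w * dz;
      grad(j, 0) -= w * dx; grad(j, 1) -= w * dy; grad(j, 2) -= w * dz;
    }
  }
  return List::create(_["dev"] = dev, _["grad"] = grad);
}

// Angle terms: theta at atom j of (i, j, k), in degrees.
// Near-degenerate (colinear) angles get NA deviates and no gradient.
// [[Rcpp::export]]
List cpp_angle_terms(NumericMatrix pos, IntegerMatrix idx, NumericVector v0,
                     NumericVector sigma, bool want_grad) {
  const int n = idx.nrow();
  const int natom = pos.nrow();
  const double rad2deg = 180.0 / M_PI;
  NumericVector dev(n);
  NumericMatrix grad(want_grad ? natom : 1, 3);
  for (int t = 0; t < n; ++t) {
    const int i = idx(t, 0) - 1, j = idx(t, 1) - 1, k = idx(t, 2) - 1;
    double u[3], v[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = pos(i, d) - pos(j, d);
      v[d] = pos(k, d) - pos(j, d);
    }
    const double nu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
    const double nv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
    if (nu < 1e-10 || nv < 1e-10) { dev[t] = NA_REAL; continue; }
    double cth = (u[0]*v[0] + u[1]*v[1] + u[2]*v[2]) / (nu * nv);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    const double sth = std::sqrt(1.0 - cth * cth);
    if (sth < 1e-8) { dev[t] = NA_REAL; continue; }
    const double theta = std::acos(cth) * rad2deg;
    const double d = (theta - v0[t]) / sigma[t];
    dev[t] = d;
    if (want_grad) {
      // dtheta/di = (cth*uhat - vhat)/(|u| sth), in radians
      const double w = 2.0 * d / sigma[t] * rad2deg;
      double gi[3], gk[3];
      for (int dd = 0; dd < 3; ++dd) {
        gi[dd] = (cth * u[dd] / nu - v[dd] / nv) / (nu * sth);
        gk[dd] = (cth * v[dd] / nv - u[dd] / nu) / (nv * sth);
        grad(i, dd) += w * gi[dd];
        grad(k, dd) += w * gk[dd];
        grad(j, dd) -= w * (gi[dd] + gk[dd]);
      }
    }
  }
  return List::create(_["dev"] = dev, _["grad"] = grad);
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Torsion terms over (i, j, k, l); deviate wrapped to (-180, 180] (divided
// by the periodicity's repeat when period > 1).
// [[Rcpp::export]]
List cpp_torsion_terms(NumericMatrix pos, IntegerMatrix idx, NumericVector v0,
                       NumericVector sigma, IntegerVector period,
                       bool want_grad) {
  const int n = idx.nrow();
  const int natom = pos.nrow();
  const double rad2deg = 180.0 / M_PI;
  NumericVector dev(n);
  NumericVector value(n);
  NumericMatrix grad(want_grad ? natom : 1, 3);
  for (int t = 0; t < n; ++t) {
    const int i = idx(t, 0) - 1, j = idx(t, 1) - 1;
    const int k = idx(t, 2) - 1, l = idx(t, 3) - 1;
    double b1[3], b2[3], b3[3], m[3], nn[3];
    for (int d = 0; d < 3; ++d) {
      b1[d] = pos(j, d) - pos(i, d);
      b2[d] = pos(k, d) - pos(j, d);
      b3[d] = pos(l, d) - pos(k, d);
    }
    cross3(b1, b2, m);
    cross3(b2, b3, nn);
    const double m2 = m[0]*m[0] + m[1]*m[1] + m[2]*m[2];
    const double n2 = nn[0]*nn[0] + nn[1]*nn[1] + nn[2]*nn[2];
    const double b2n = std::sqrt(b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2]);
    if (m2 < 1e-14 || n2 < 1e-14 || b2n < 1e-10) {
      dev[t] = NA_REAL; value[t] = NA_REAL; continue;
    }
    double mxn[3];
    cross3(m, nn, mxn);
    const double y = (mxn[0]*b2[0] + mxn[1]*b2[1] + mxn[2]*b2[2]) / b2n;
    const double x = m[0]*nn[0] + m[1]*nn[1] + m[2]*nn[2];
    const double phi = std::atan2(y, x) * rad2deg;
    value[t] = phi;
    const int p = period[t] > 0 ? period[t] : 1;
    const double rep = 360.0 / p;
    double delta = phi - v0[t];
    delta -= rep * std::floor(delta / rep + 0.5);
    const double half = 180.0 / p;
    if (delta <= -half) delta += rep;
    if (delta > half) delta -= rep;
    const double d = delta / sigma[t];
    dev[t] = d;
    if (want_grad) {
      const double w = 2.0 * d / sigma[t] * rad2deg;
      const double s1 = (b1[0]*b2[0] + b1[1]*b2[1] + b1[2]*b2[2]) / (b2n*b2n);
      const double s2 = (b3[0]*b2[0] + b3[1]*b2[1] + b3[2]*b2[2]) / (b2n*b2n);
      for (int d3 = 0; d3 < 3; ++d3) {
        const double dpi = -b2n / m2 * m[d3];
        const double dpl = b2n / n2 * nn[d3];
        const double dpj = (s1 - 1.0) * dpi - s2 * dpl;
        const double dpk = (s2 - 1.0) * dpl - s1 * dpi;
        grad(i, d3) += w * dpi;
        grad(j, d3) += w * dpj;
        grad(k, d3) += w * dpk;
        grad(l, d3) += w * dpl;
      }
    }
  }
  return List::create(_["dev"] = dev, _["value"] = value, _["grad"] = grad);
}

// Normalized 12-6 Lennard-Jones: E(r) = (r0/r)^12 - 2 (r0/r)^6, min -1 at r0.
// [[Rcpp::export]]
List cpp_lj_terms(NumericMatrix pos, IntegerMatrix idx, NumericVector r0,
                  bool want_grad) {
  const int n = idx.nrow();
  const int natom = pos.nrow();
  NumericVector e(n), r(n);
  NumericMatrix grad(want_grad ? natom : 1, 3);
  for (int t = 0; t < n; ++t) {
    const int i = idx(t, 0) - 1, j = idx(t, 1) - 1;
    const double dx = pos(i, 0) - pos(j, 0);
    const double dy = pos(i, 1) - pos(j, 1);
    const double dz = pos(i, 2) - pos(j, 2);
    const double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
    r[t] = rr;
    if (rr < 1e-10) stop("coincident non-bonded atoms (r = 0)");
    const double s = r0[t] / rr;
    const double s6 = s * s * s * s * s * s;
    e[t] = s6 * s6 - 2.0 * s6;
    if (want_grad) {
      const double dedr = -12.0 * (s6 * s6 - s6) / rr;
      const double w = dedr / rr;
      grad(i, 0) += w * dx; grad(i, 1) += w * dy; grad(i, 2) += w * dz;
      grad(j, 0) -= w * dx; grad(j, 1) -= w * dy; grad(j, 2) -= w * dz;
    }
  }
  return List::create(_["e"] = e, _["r"] = r, _["grad"] = grad);
}
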