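// Shared numerical primitives for the nested FSI engine and the exported
// operator wrappers. Everything here is dimension-agnostic unless noted.
#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

namespace fsi {

// ---- cubic spline kernel, support radius 2h --------------------------------
inline double kernel_sigma(double h, int d) {
  if (d == 1) return 2.0 / (3.0 * h);
  if (d == 2) return 10.0 / (7.0 * M_PI * h * h);
  return 1.0 / (M_PI * h * h * h);
}

inline double kernel_w(double r, double h, int d) {
  const double q = r / h;
  if (q >= 2.0) return 0.0;
  const double f = (q < 1.0)
    ? 1.0 - 1.5 * q * q + 0.75 * q * q * q
    : 0.25 * (2.0 - q) * (2.0 - q) * (2.0 - q);
  return kernel_sigma(h, d) * f;
}

// dW/dr (negative inside the support)
inline double kernel_dwdr(double r, double h, int d) {
  const double q = r / h;
  if (q >= 2.0) return 0.0;
  const double fp = (q < 1.0)
    ? (-3.0 * q + 2.25 * q * q)
    : (-0.75 * (2.0 - q) * (2.0 - q));
  return kernel_sigma(h, d) * fp / h;
}

// ---- point-to-segment distance (2-D) ---------------------------------------
// Returns the distance; t gets the segment parameter in [0,1], cp the closest
// point.
inline double pt_seg(const double* p, const double* a, const double* b,
                     double& t, double* cp) {
  const double abx = b[0] - a[0], aby = b[1] - a[1];
  const double L2 = abx * abx + aby * aby;
  t = 0.0;
  if (L2 > 0.0) {
    t = ((p[0] - a[0]) * abx + (p[1] - a[1]) * aby) / L2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  cp[0] = a[0] + t * abx;
  cp[1] = a[1] + t * aby;
  const double dx = p[0] - cp[0], dy = p[1] - cp[1];
  return std::sqrt(dx * dx + dy * dy);
}

// squared-distance variant (avoids the sqrt during candidate search)
inline double pt_seg2(const double* p, const double* a, const double* b,
                      double& t, double* cp) {
  const double abx = b[0] - a[0], aby = b[1] - a[1];
  const double L2 = abx * abx + aby * aby;
  t = 0.0;
  if (L2 > 0.0) {
    t = ((p[0] - a[0]) * abx + (p[1] - a[1]) * aby) / L2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  cp[0] = a[0] + t * abx;
  cp[1] = a[1] + t * aby;
  const double dx = p[0] - cp[0], dy = p[1] - cp[1];
  return dx * dx + dy * dy;
}

// ---- uniform cell grid over 2-D points -------------------------------------
struct CellGrid {
  double xmin, ymin, cell;
  int nx, ny;
  std::vector<int> head;   // first index per cell, -1 empty
  std::vector<int> nxt;    // linked list over items

  void build(const std::vector<double>& x, const std::vector<double>& y,
             int n, double cell_size) {
    cell = cell_size;
    xmin = std::numeric_limits<double>::max();
    ymin = std::numeric_limits<double>::max();
    double xmax = -xmin, ymax = -ymin;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    if (n == 0) { xmin = ymin = 0.0; xmax = ymax = 0.0; }
    nx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
    head.assign((size_t)nx * ny, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      const int c = cell_of(x[i], y[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  inline int cell_of(double px, double py) const {
    const int cx = clampi((int)std::floor((px - xmin) / cell), 0, nx - 1);
    const int cy = clampi((int)std::floor((py - ymin) / cell), 0, ny - 1);
    return cy * nx + cx;
  }
};

// ---- generalized Maxwell deviatoric update ---------------------------------
// One mode, 4 stress components (xx, yy, zz, xy), exponential internal
// variable recurrence with midpoint weighting of the strain increment.
inline void maxwell_advance(double* sk, const double* de, double Gk,
                            double tauk, double dt) {
  const double e1 = std::exp(-dt / tauk);
  const double e2 = std::exp(-0.5 * dt / tauk);
  for (int c = 0; c < 4; ++c) sk[c] = e1 * sk[c] + 2.0 * Gk * e2 * de[c];
}

// ---- SPH pairwise interaction ----------------------------------------------
// Continuity (Monaghan form) and momentum (symmetric pressure + Monaghan
// artificial viscosity) contributions of one particle pair, any dimension.
// Adds into drho_* and acc_* (length d). Skips pairs outside the 2h support.
inline void sph_pair(const double* xi, const double* xj,
                     const double* vi, const double* vj,
                     double mi, double mj, double rhoi, double rhoj,
                     double pi_, double pj_,
                     double h, double alpha, double beta, double eps,
                     double c0, int d,
                     double& drho_i, double& drho_j,
                     double* acc_i, double* acc_j) {
  double dx[3], dv[3], r2 = 0.0;
  for (int k = 0; k < d; ++k) {
    dx[k] = xi[k] - xj[k];
    dv[k] = vi[k] - vj[k];
    r2 += dx[k] * dx[k];
  }
  const double r = std::sqrt(r2);
  if (r >= 2.0 * h || r == 0.0) return;
  const double dwdr = kernel_dwdr(r, h, d);
  // grad_i W_ij = (x_i - x_j)/r * dW/dr
  double vdotx = 0.0;
  for (int k = 0; k < d; ++k) vdotx += dv[k] * dx[k];
  const double gradfac = dwdr / r;  // multiply by dx[k]
  // continuity: drho_i/dt += m_j (v_i - v_j) . grad_i W_ij (symmetric)
  const double cont = vdotx * gradfac;
  drho_i += mj * cont;
  drho_j += mi * cont;
  // artificial viscosity (approaching pairs only)
  double Pi = 0.0;
  if (vdotx < 0.0 && (alpha > 0.0 || beta > 0.0)) {
    const double mu = h * vdotx / (r2 + eps * h * h);
    const double rbar = 0.5 * (rhoi + rhoj);
    Pi = (-alpha * c0 * mu + beta * mu * mu) / rbar;
  }
  const double fac = (pi_ / (rhoi * rhoi) + pj_ / (rhoj * rhoj) + Pi) * gradfac;
  for (int k = 0; k < d; ++k) {
    acc_i[k] -= mj * fac * dx[k];
    acc_j[k] += mi * fac * dx[k];
  }
}

// von Mises from (xx, yy, zz, xy)
inline double von_mises4(const double* s) {
  const double a = s[0] - s[1], b = s[1] - s[2], c = s[2] - s[0];
  return std::sqrt(0.5 * (a * a + b * b + c * c) + 3.0 * s[3] * s[3]);
}

} // namespace fsi
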