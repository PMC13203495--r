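// Exported operator-level wrappers. These share the pairwise / element-level
// physics with the coupled engine (see fsi_common.h), exposed individually so
// each operator can be exercised and tested on its own.
#include "fsi_common.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_kernel_value(NumericVector r, double h, int d) {
  const int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (r[i] < 0) stop("kernel separation must be nonnegative");
    out[i] = fsi::kernel_w(r[i], h, d);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_kernel_grad(NumericMatrix dx, double h) {
  const int n = dx.nrow(), d = dx.ncol();
  NumericMatrix out(n, d);
  for (int i = 0; i < n; ++i) {
    double r2 = 0.0;
    for (int k = 0; k < d; ++k) r2 += dx(i, k) * dx(i, k);
    const double r = std::sqrt(r2);
    if (r == 0.0) continue;
    const double g = fsi::kernel_dwdr(r, h, d) / r;
    for (int k = 0; k < d; ++k) out(i, k) = g * dx(i, k);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_interpolate(NumericMatrix query, NumericMatrix pos,
                     NumericVector mass, NumericVector rho,
                     NumericVector vals, double h, bool shepard) {
  const int nq = query.nrow(), np = pos.nrow(), d = pos.ncol();
  NumericVector out(nq);
  LogicalVector empty(nq);
  for (int q = 0; q < nq; ++q) {
    double num = 0.0, den = 0.0;
    bool any = false;
    for (int j = 0; j < np; ++j) {
      double r2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double dd = query(q, k) - pos(j, k);
        r2 += dd * dd;
      }
      const double r = std::sqrt(r2);
      if (r >= 2.0 * h) continue;
      any = true;
      const double w = fsi::kernel_w(r, h, d) * mass[j] / rho[j];
      num += w * vals[j];
      den += w;
    }
    empty[q] = !any;
    if (!any) { out[q] = 0.0; continue; }
    out[q] = shepard ? (den > 0.0 ? num / den : 0.0) : num;
  }
  return List::create(_["value"] = out, _["empty"] = empty);
}

// [[Rcpp::export]]
List cpp_sph_rates(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                   NumericVector rho, NumericVector p, double h,
                   double alpha, double beta, double eps, double c0,
                   NumericVector g) {
  const int n = pos.nrow(), d = pos.ncol();
  NumericVector drho(n);
  NumericMatrix acc(n, d);
  std::vector<double> x(n * 3, 0.0), v(n * 3, 0.0), a(n * 3, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) {
      x[3 * i + k] = pos(i, k);
      v[3 * i + k] = vel(i, k);
    }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      fsi::sph_pair(&x[3 * i], &x[3 * j], &v[3 * i], &v[3 * j],
                    mass[i], mass[j], rho[i], rho[j], p[i], p[j],
                    h, alpha, beta, eps, c0, d,
                    drho[i], drho[j], &a[3 * i], &a[3 * j]);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) acc(i, k) = a[3 * i + k] + g[k];
  return List::create(_["drho"] = drho, _["acc"] = acc);
}

// [[Rcpp::export]]
NumericVector cpp_shepard_density(NumericMatrix pos, NumericVector mass,
                                  NumericVector rho, double h) {
  const int n = pos.nrow(), d = pos.ncol();
  NumericVector out(n);
  const double w0 = fsi::kernel_w(0.0, h, d);
  for (int i = 0; i < n; ++i) {
    double num = mass[i] * w0, den = mass[i] / rho[i] * w0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double r2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double dd = pos(i, k) - pos(j, k);
        r2 += dd * dd;
      }
      const double r = std::sqrt(r2);
      if (r >= 2.0 * h) continue;
      const double w = fsi::kernel_w(r, h, d);
      num += mass[j] * w;
      den += mass[j] / rho[j] * w;
    }
    out[i] = num / den;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double support) {
  // uniform cell list, cell size = support; returns i<j pairs (1-based)
  const int n = pos.nrow();
  if (pos.ncol() != 2) stop("cell-list neighbor search is 2-D");
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  fsi::CellGrid grid;
  grid.build(x, y, n, support);
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i) {
    const int cx = grid.clampi((int)std::floor((x[i] - grid.xmin) / grid.cell), 0, grid.nx - 1);
    const int cy = grid.clampi((int)std::floor((y[i] - grid.ymin) / grid.cell), 0, grid.ny - 1);
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        const int ncx = cx + ox, ncy = cy + oy;
        if (ncx < 0 || ncx >= grid.nx || ncy < 0 || ncy >= grid.ny) continue;
        for (int j = grid.head[(size_t)ncy * grid.nx + ncx]; j >= 0; j = grid.nxt[j]) {
          if (j <= i) continue;
          const double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy < support * support) {
            pi.push_back(i + 1);
            pj.push_back(j + 1);
          }
        }
      }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}

// [[Rcpp::export]]
List cpp_contact_forces(NumericMatrix ppos, NumericMatrix surf, bool closed,
                        int orient, double kc) {
  // Penalty contact of points against a 2-D polyline (CCW ordering assumed;
  // orient = +1 when the non-solid side is the polygon-outward side).
  const int np = ppos.nrow(), ns = surf.nrow();
  const int nseg = closed ? ns : ns - 1;
  NumericMatrix force(np, 2), nodal(ns, 2);
  NumericVector delta(np), tpar(np);
  IntegerVector segidx(np);
  for (int i = 0; i < np; ++i) {
    double best = std::numeric_limits<double>::max(), bt = 0.0, bcp[2] = {0, 0};
    int bseg = -1;
    const double p[2] = { ppos(i, 0), ppos(i, 1) };
    for (int s = 0; s < nseg; ++s) {
      const int s2 = (s + 1) % ns;
      const double a[2] = { surf(s, 0), surf(s, 1) };
      const double b[2] = { surf(s2, 0), surf(s2, 1) };
      double t, cp[2];
      const double dd = fsi::pt_seg(p, a, b, t, cp);
      if (dd < best) { best = dd; bt = t; bseg = s; bcp[0] = cp[0]; bcp[1] = cp[1]; }
    }
    segidx[i] = bseg + 1;
    tpar[i] = bt;
    if (bseg < 0) continue;
    const int s2 = (bseg + 1) % ns;
    double ex = surf(s2, 0) - surf(bseg, 0), ey = surf(s2, 1) - surf(bseg, 1);
    const double L = std::sqrt(ex * ex + ey * ey);
    if (L == 0.0) continue;
    // polygon-outward normal for CCW ordering, flipped by orient
    double nxv = orient * (ey / L), nyv = orient * (-ex / L);
    const double signed_d = (p[0] - bcp[0]) * nxv + (p[1] - bcp[1]) * nyv;
    if (signed_d < 0.0) {
      const double del = -signed_d;
      delta[i] = del;
      const double fx = kc * del * nxv, fy = kc * del * nyv;
      force(i, 0) = fx; force(i, 1) = fy;
      nodal(bseg, 0) -= fx * (1.0 - bt); nodal(bseg, 1) -= fy * (1.0 - bt);
      nodal(s2, 0) -= fx * bt;           nodal(s2, 1) -= fy * bt;
    }
  }
  return List::create(_["force"] = force, _["delta"] = delta,
                      _["segment"] = segidx, _["t"] = tpar,
                      _["nodal"] = nodal);
}

// [[Rcpp::export]]
NumericVector cpp_min_dist_polyline(NumericMatrix pts, NumericMatrix poly,
                                    bool closed) {
  const int np = pts.nrow(), ns = poly.nrow();
  const int nseg = closed ? ns : ns - 1;
  if (ns < 2) stop("surface must have at least two nodes");
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double p[2] = { pts(i, 0), pts(i, 1) };
    double best = std::numeric_limits<double>::max();
    for (int s = 0; s < nseg; ++s) {
      const int s2 = (s + 1) % ns;
      const double a[2] = { poly(s, 0), poly(s, 1) };
      const double b[2] = { poly(s2, 0), poly(s2, 1) };
      double t, cp[2];
      best = std::min(best, fsi::pt_seg(p, a, b, t, cp));
    }
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_min_dist_trimesh(NumericMatrix pts, NumericMatrix V,
                                   IntegerMatrix F) {
  // exact point-to-triangle minimum distance (3-D), brute force over faces
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double best = std::numeric_limits<double>::max();
    for (int f = 0; f < nf; ++f) {
      double a[3], b[3], c[3];
      for (int k = 0; k < 3; ++k) {
        a[k] = V(F(f, 0) - 1, k);
        b[k] = V(F(f, 1) - 1, k);
        c[k] = V(F(f, 2) - 1, k);
      }
      // Ericson-style closest point on triangle
      double ab[3], ac[3], ap[3];
      for (int k = 0; k < 3; ++k) {
        ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
      }
      auto dot3 = [](const double* u, const double* v) {
        return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
      };
      const double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
      double q[3];
      if (d1 <= 0 && d2 <= 0) { for (int k = 0; k < 3; ++k) q[k] = a[k]; }
      else {
        double bp[3], cp_[3];
        for (int k = 0; k < 3; ++k) { bp[k] = p[k] - b[k]; cp_[k] = p[k] - c[k]; }
        const double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
        const double d5 = dot3(ab, cp_), d6 = dot3(ac, cp_);
        if (d3 >= 0 && d4 <= d3) { for (int k = 0; k < 3; ++k) q[k] = b[k]; }
        else if (d6 >= 0 && d5 <= d6) { for (int k = 0; k < 3; ++k) q[k] = c[k]; }
        else {
          const double vc = d1 * d4 - d3 * d2;
          if (vc <= 0 && d1 >= 0 && d3 <= 0) {
            const double t = d1 / (d1 - d3);
            for (int k = 0; k < 3; ++k) q[k] = a[k] + t * ab[k];
          } else {
            const double vb = d5 * d2 - d1 * d6;
            if (vb <= 0 && d2 >= 0 && d6 <= 0) {
              const double t = d2 / (d2 - d6);
              for (int k = 0; k < 3; ++k) q[k] = a[k] + t * ac[k];
            } else {
              const double va = d3 * d6 - d5 * d4;
              if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
                const double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
                for (int k = 0; k < 3; ++k) q[k] = b[k] + t * (c[k] - b[k]);
              } else {
                const double denom = 1.0 / (va + vb + vc);
                const double v = vb * denom, w = vc * denom;
                for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * v + ac[k] * w;
              }
            }
          }
        }
      }
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) r2 += (p[k] - q[k]) * (p[k] - q[k]);
      best = std::min(best, std::sqrt(r2));
    }
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxwell_update(NumericVector eps_new, NumericVector eps_prev,
                        NumericMatrix sk, double dt, double K, double Ginf,
                        NumericVector Gk, NumericVector tauk) {
  // Point-wise constitutive update. Strain as (xx, yy, zz, xy).
  // sk: nmode x 4 mode stresses; returns total stress + updated state.
  const int nm = Gk.size();
  double tr_n = eps_new[0] + eps_new[1] + eps_new[2];
  double dev_n[4] = { eps_new[0] - tr_n / 3.0, eps_new[1] - tr_n / 3.0,
                      eps_new[2] - tr_n / 3.0, eps_new[3] };
  double tr_p = eps_prev[0] + eps_prev[1] + eps_prev[2];
  double dev_p[4] = { eps_prev[0] - tr_p / 3.0, eps_prev[1] - tr_p / 3.0,
                      eps_prev[2] - tr_p / 3.0, eps_prev[3] };
  double de[4];
  for (int c = 0; c < 4; ++c) de[c] = dev_n[c] - dev_p[c];
  NumericMatrix sk_new(nm, 4);
  double sig[4] = { K * tr_n, K * tr_n, K * tr_n, 0.0 };
  for (int c = 0; c < 4; ++c) sig[c] += 2.0 * Ginf * dev_n[c];
  for (int m = 0; m < nm; ++m) {
    double s[4] = { sk(m, 0), sk(m, 1), sk(m, 2), sk(m, 3) };
    fsi::maxwell_advance(s, de, Gk[m], tauk[m], dt);
    for (int c = 0; c < 4; ++c) { sk_new(m, c) = s[c]; sig[c] += s[c]; }
  }
  return List::create(
    _["sigma"] = NumericVector::create(sig[0], sig[1], sig[2], sig[3]),
    _["sk"] = sk_new);
}

// [[Rcpp::export]]
List cpp_internal_force(NumericMatrix X, IntegerMatrix tri, NumericMatrix u,
                        double K, double Ginf, NumericVector Gk,
                        NumericVector tauk, double dt,
                        NumericMatrix eprev, NumericMatrix skflat,
                        bool advance) {
  // Linear-triangle small-strain assembly (plane strain, unit thickness).
  // eprev: ne x 4 previous deviatoric strain; skflat: ne x (4*nmode) mode
  // stresses. If advance, Maxwell modes are stepped by dt; otherwise forces
  // are assembled from the stored mode stresses (static evaluation).
  const int nn = X.nrow(), ne = tri.nrow(), nm = Gk.size();
  NumericMatrix f(nn, 2), sig_out(ne, 4), eprev_new(clone(eprev));
  NumericMatrix sk_new(clone(skflat));
  NumericMatrix strain_out(ne, 4);
  for (int e = 0; e < ne; ++e) {
    const int i = tri(e, 0) - 1, j = tri(e, 1) - 1, k = tri(e, 2) - 1;
    const double x1 = X(i, 0), y1 = X(i, 1), x2 = X(j, 0), y2 = X(j, 1),
                 x3 = X(k, 0), y3 = X(k, 1);
    const double twoA = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
    if (twoA <= 1e-14)
      stop("degenerate element %d (signed area %g)", e + 1, twoA / 2.0);
    const double A = 0.5 * twoA;
    const double dNdx[3] = { (y2 - y3) / twoA, (y3 - y1) / twoA, (y1 - y2) / twoA };
    const double dNdy[3] = { (x3 - x2) / twoA, (x1 - x3) / twoA, (x2 - x1) / twoA };
    const int id[3] = { i, j, k };
    double exx = 0, eyy = 0, exy = 0;
    for (int a = 0; a < 3; ++a) {
      exx += dNdx[a] * u(id[a], 0);
      eyy += dNdy[a] * u(id[a], 1);
      exy += 0.5 * (dNdy[a] * u(id[a], 0) + dNdx[a] * u(id[a], 1));
    }
    const double tr = exx + eyy;
    double dev[4] = { exx - tr / 3.0, eyy - tr / 3.0, -tr / 3.0, exy };
    double sig[4] = { K * tr, K * tr, K * tr, 0.0 };
    for (int c = 0; c < 4; ++c) sig[c] += 2.0 * Ginf * dev[c];
    for (int m = 0; m < nm; ++m) {
      double s[4];
      for (int c = 0; c < 4; ++c) s[c] = skflat(e, 4 * m + c);
      if (advance) {
        double de[4];
        for (int c = 0; c < 4; ++c) de[c] = dev[c] - eprev(e, c);
        fsi::maxwell_advance(s, de, Gk[m], tauk[m], dt);
        for (int c = 0; c < 4; ++c) sk_new(e, 4 * m + c) = s[c];
      }
      for (int c = 0; c < 4; ++c) sig[c] += s[c];
    }
    if (advance)
      for (int c = 0; c < 4; ++c) eprev_new(e, c) = dev[c];
    for (int c = 0; c < 4; ++c) sig_out(e, c) = sig[c];
    strain_out(e, 0) = exx; strain_out(e, 1) = eyy;
    strain_out(e, 2) = 0.0; strain_out(e, 3) = exy;
    for (int a = 0; a < 3; ++a) {
      f(id[a], 0) -= A * (dNdx[a] * sig[0] + dNdy[a] * sig[3]);
      f(id[a], 1) -= A * (dNdy[a] * sig[1] + dNdx[a] * sig[3]);
    }
  }
  return List::create(_["force"] = f, _["sigma"] = sig_out,
                      _["strain"] = strain_out, _["eprev"] = eprev_new,
                      _["sk"] = sk_new);
}
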