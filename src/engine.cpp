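// Coupled explicit time stepper: weakly compressible SPH fluids + linear
// triangle viscoelastic solids + penalty contact. 2-D, unit thickness.
//
// Per step (matching the driver's documented ordering):
//   1. impose prescribed rigid-roll motion on driven solid nodes
//   2. SPH continuity/EOS/momentum rates for every fluid domain
//      (periodic Shepard density reinitialization)
//   3. penalty contact coupling (particle<->surface and node<->surface)
//   4. solid internal forces (generalized Maxwell) + explicit integration
//   5. fluid integration; sampling of metrics at the output cadence
#include "fsi_common.h"
using namespace Rcpp;

namespace {

struct Fluid {
  int n = 0;
  std::vector<double> x, y, vx, vy, m, rho, p, ax, ay, drho;
  double rho0 = 0, c0 = 0, h = 0, alpha = 0, beta = 0, eps = 0;
  double gx = 0, gy = 0;
  // CSR cell grid scratch
  std::vector<int> cell_of, order, cell_start, cnt;
  double gxmin = 0, gymin = 0, gcell = 0;
  int gnx = 0, gny = 0;
};

// Sorted (CSR) cell grid rebuild for a fluid; cell size 2h.
static void fluid_grid(Fluid& f) {
  const int n = f.n;
  f.gcell = 2.0 * f.h;
  double xmin = f.x[0], xmax = f.x[0], ymin = f.y[0], ymax = f.y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, f.x[i]); xmax = std::max(xmax, f.x[i]);
    ymin = std::min(ymin, f.y[i]); ymax = std::max(ymax, f.y[i]);
  }
  f.gxmin = xmin; f.gymin = ymin;
  f.gnx = (int)std::floor((xmax - xmin) / f.gcell) + 1;
  f.gny = (int)std::floor((ymax - ymin) / f.gcell) + 1;
  if (!std::isfinite(xmax - xmin) || (double)f.gnx * f.gny > 2e7)
    Rcpp::stop("numerical instability: fluid domain exploded (extent %g m)",
               xmax - xmin);
  const int ncell = f.gnx * f.gny;
  f.cell_of.resize(n); f.order.resize(n);
  f.cell_start.assign(ncell + 1, 0);
  for (int i = 0; i < n; ++i) {
    int cx = (int)((f.x[i] - xmin) / f.gcell);
    int cy = (int)((f.y[i] - ymin) / f.gcell);
    if (cx >= f.gnx) cx = f.gnx - 1;
    if (cy >= f.gny) cy = f.gny - 1;
    f.cell_of[i] = cy * f.gnx + cx;
    f.cell_start[f.cell_of[i] + 1]++;
  }
  for (int c = 0; c < ncell; ++c) f.cell_start[c + 1] += f.cell_start[c];
  f.cnt.assign(ncell, 0);
  for (int i = 0; i < n; ++i) {
    const int c = f.cell_of[i];
    f.order[f.cell_start[c] + f.cnt[c]++] = i;
  }
}

struct Mode { double G, tau, e1, e2; };

struct Solid {
  int nn = 0, ne = 0;
  std::vector<double> X, Y;          // rest positions
  std::vector<int> t1, t2, t3;       // element nodes (0-based)
  std::vector<double> area, dNdx, dNdy;  // per element (3 grads each)
  std::vector<double> mass;
  double K = 0, Ginf = 0, ra = 0;
  std::vector<Mode> modes;
  std::vector<double> ux, uy, vx, vy, fx, fy;
  std::vector<double> eprev;         // ne*4 deviatoric strain
  std::vector<double> sk;            // ne*4*nmode
  std::vector<double> sig;           // ne*4 current stress
  std::vector<double> strn;          // ne*4 current strain (xx,yy,zz,xy)
  std::vector<int> fixedx, fixedy;   // 0/1 per node
  std::vector<int> presc;            // prescribed (rigid roll) nodes
  // rigid-body treatment (e.g. the cranial vault, whose stiffness is orders
  // above every load scale here): 3 DOF integrated from the total force and
  // torque on its nodes (tied slave nodes included)
  bool rigid = false;
  double cx0 = 0, cy0 = 0, M = 0, I = 0;
  double cdx = 0, cdy = 0, vcx = 0, vcy = 0, phi = 0, omega = 0;
};

struct Surface {
  int solid = 0, orient = 1;
  std::vector<int> nodes;  // closed CCW loop, 0-based
};

struct Contact {
  int type = 0;            // 0 = fluid particles, 1 = solid nodes
  int fluid = -1, solid = -1, surface = 0;
  std::vector<int> nodes;  // for type 1
  double kc = 0, cap = 0;
  // Wall standoff: the contact surface for particle centres sits this far
  // on the fluid side of the solid surface (half a particle spacing, the
  // usual SPH wall convention), so the lattice engages the wall with zero
  // force at rest and any approach immediately builds pressure.
  double standoff = 0;
  // No-separation (wetted) range: within this distance beyond the standoff
  // plane the interface sustains tension (tapered to zero at the range), the
  // thin-film suction a wetted fluid layer supports before cavitating.
  // Zero = unilateral (push-only) contact.
  double tension_range = 0;
  // candidate-search reach: points farther than this from a segment cannot
  // interact (sized from standoff + tension range + a penetration margin)
  double reach = 0;
  // wetted-film bonds: a point within the wetted band bonds to the wall at
  // its formation thickness (force-free at bonding), so the seeded state is
  // exactly quiescent and the film acts as a bilateral spring bed about the
  // bonded thickness thereafter; points arriving later bond on first touch
  // at the standoff plane
  std::vector<char> latched;
  std::vector<double> neutral;
};

struct Tie { int sa, na, sb, nb; };  // master (sa,na) <- slave (sb,nb)

struct Landmark { int solid, node, surface; };

inline void surf_positions(const Solid& s, const Surface& sf,
                           std::vector<double>& px, std::vector<double>& py) {
  const size_t n = sf.nodes.size();
  px.resize(n); py.resize(n);
  for (size_t k = 0; k < n; ++k) {
    const int i = sf.nodes[k];
    px[k] = s.X[i] + s.ux[i];
    py[k] = s.Y[i] + s.uy[i];
  }
}

// Contact of a point set against a surface, candidates found through a cell
// grid over the segment midpoints (cell size >= max segment length + reach).
struct SurfGrid {
  std::vector<double> mx, my;  // segment midpoints
  fsi::CellGrid grid;
  double cell = 0;
  void build(const std::vector<double>& px, const std::vector<double>& py,
             double reach) {
    const int ns = (int)px.size();
    mx.resize(ns); my.resize(ns);
    double maxlen = 0;
    for (int s = 0; s < ns; ++s) {
      const int s2 = (s + 1) % ns;
      mx[s] = 0.5 * (px[s] + px[s2]);
      my[s] = 0.5 * (py[s] + py[s2]);
      const double dx = px[s2] - px[s], dy = py[s2] - py[s];
      maxlen = std::max(maxlen, std::sqrt(dx * dx + dy * dy));
    }
    cell = maxlen + 2.0 * reach;
    grid.build(mx, my, ns, cell);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_fsi_engine(List fluids_in, List solids_in, List surfaces_in,
                    List contacts_in, List ties_in, List landmarks_in,
                    NumericVector theta, double dt, int nsteps,
                    int sample_every, int snap_every, int shepard_every,
                    int stress_solid, bool debug) {
  // ---- unpack ---------------------------------------------------------------
  std::vector<Fluid> fl(fluids_in.size());
  for (int q = 0; q < fluids_in.size(); ++q) {
    List L = fluids_in[q];
    NumericMatrix pos = L["pos"], vel = L["vel"];
    NumericVector m = L["mass"], rho = L["rho"], g = L["g"];
    Fluid& f = fl[q];
    f.n = pos.nrow();
    f.x.resize(f.n); f.y.resize(f.n); f.vx.resize(f.n); f.vy.resize(f.n);
    f.m.resize(f.n); f.rho.resize(f.n); f.p.assign(f.n, 0.0);
    f.ax.assign(f.n, 0.0); f.ay.assign(f.n, 0.0); f.drho.assign(f.n, 0.0);
    for (int i = 0; i < f.n; ++i) {
      f.x[i] = pos(i, 0); f.y[i] = pos(i, 1);
      f.vx[i] = vel(i, 0); f.vy[i] = vel(i, 1);
      f.m[i] = m[i]; f.rho[i] = rho[i];
    }
    f.rho0 = L["rho0"]; f.c0 = L["c0"]; f.h = L["h"];
    f.alpha = L["alpha"]; f.beta = L["beta"]; f.eps = L["eps"];
    f.gx = g[0]; f.gy = g[1];
  }

  std::vector<Solid> so(solids_in.size());
  for (int q = 0; q < solids_in.size(); ++q) {
    List L = solids_in[q];
    NumericMatrix X = L["X"];
    IntegerMatrix tri = L["tri"];
    NumericVector mass = L["mass"], Gk = L["Gk"], tauk = L["tauk"];
    LogicalMatrix fixed = L["fixed"];
    IntegerVector presc = L["prescribed"];
    Solid& s = so[q];
    s.nn = X.nrow(); s.ne = tri.nrow();
    s.X.resize(s.nn); s.Y.resize(s.nn);
    for (int i = 0; i < s.nn; ++i) { s.X[i] = X(i, 0); s.Y[i] = X(i, 1); }
    s.t1.resize(s.ne); s.t2.resize(s.ne); s.t3.resize(s.ne);
    s.area.resize(s.ne); s.dNdx.resize(3 * s.ne); s.dNdy.resize(3 * s.ne);
    for (int e = 0; e < s.ne; ++e) {
      const int i = tri(e, 0) - 1, j = tri(e, 1) - 1, k = tri(e, 2) - 1;
      s.t1[e] = i; s.t2[e] = j; s.t3[e] = k;
      const double x1 = s.X[i], y1 = s.Y[i], x2 = s.X[j], y2 = s.Y[j],
                   x3 = s.X[k], y3 = s.Y[k];
      const double twoA = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
      if (twoA <= 1e-14)
        stop("solid %d: degenerate element %d", q + 1, e + 1);
      s.area[e] = 0.5 * twoA;
      s.dNdx[3 * e + 0] = (y2 - y3) / twoA;
      s.dNdx[3 * e + 1] = (y3 - y1) / twoA;
      s.dNdx[3 * e + 2] = (y1 - y2) / twoA;
      s.dNdy[3 * e + 0] = (x3 - x2) / twoA;
      s.dNdy[3 * e + 1] = (x1 - x3) / twoA;
      s.dNdy[3 * e + 2] = (x2 - x1) / twoA;
    }
    s.mass.assign(mass.begin(), mass.end());
    s.K = L["K"]; s.Ginf = L["Ginf"]; s.ra = L["ra"];
    const int nm = Gk.size();
    s.modes.resize(nm);
    for (int m = 0; m < nm; ++m) {
      s.modes[m].G = Gk[m];
      s.modes[m].tau = tauk[m];
      s.modes[m].e1 = std::exp(-dt / tauk[m]);
      s.modes[m].e2 = std::exp(-0.5 * dt / tauk[m]);
    }
    s.ux.assign(s.nn, 0.0); s.uy.assign(s.nn, 0.0);
    s.vx.assign(s.nn, 0.0); s.vy.assign(s.nn, 0.0);
    s.fx.assign(s.nn, 0.0); s.fy.assign(s.nn, 0.0);
    s.eprev.assign((size_t)s.ne * 4, 0.0);
    s.sk.assign((size_t)s.ne * 4 * std::max(nm, 1), 0.0);
    s.sig.assign((size_t)s.ne * 4, 0.0);
    s.strn.assign((size_t)s.ne * 4, 0.0);
    s.fixedx.assign(s.nn, 0); s.fixedy.assign(s.nn, 0);
    for (int i = 0; i < s.nn; ++i) {
      s.fixedx[i] = fixed(i, 0) ? 1 : 0;
      s.fixedy[i] = fixed(i, 1) ? 1 : 0;
    }
    s.presc.assign(presc.begin(), presc.end());
    for (auto& v : s.presc) v -= 1;
    s.rigid = as<bool>(L["rigid"]);
    if (s.rigid) {
      double sm = 0, sx = 0, sy = 0;
      for (int i = 0; i < s.nn; ++i) {
        sm += s.mass[i]; sx += s.mass[i] * s.X[i]; sy += s.mass[i] * s.Y[i];
      }
      s.cx0 = sx / sm; s.cy0 = sy / sm;
      s.M = sm;
      s.I = 0;
      for (int i = 0; i < s.nn; ++i) {
        const double rx = s.X[i] - s.cx0, ry = s.Y[i] - s.cy0;
        s.I += s.mass[i] * (rx * rx + ry * ry);
      }
    }
  }

  std::vector<Surface> sf(surfaces_in.size());
  for (int q = 0; q < surfaces_in.size(); ++q) {
    List L = surfaces_in[q];
    IntegerVector nodes = L["nodes"];
    sf[q].solid = (int)L["solid"] - 1;
    sf[q].orient = L["orient"];
    sf[q].nodes.assign(nodes.begin(), nodes.end());
    for (auto& v : sf[q].nodes) v -= 1;
  }

  std::vector<Contact> ct(contacts_in.size());
  for (int q = 0; q < contacts_in.size(); ++q) {
    List L = contacts_in[q];
    Contact& c = ct[q];
    c.type = L["type"];
    c.surface = (int)L["surface"] - 1;
    c.kc = L["kc"]; c.cap = L["cap"]; c.standoff = L["standoff"];
    c.tension_range = L["tension_range"]; c.reach = L["reach"];
    if (c.type == 0) {
      c.fluid = (int)L["fluid"] - 1;
      c.latched.assign(fl[c.fluid].n, 0);
      c.neutral.assign(fl[c.fluid].n, c.standoff);
    } else {
      c.solid = (int)L["solid"] - 1;
      IntegerVector nodes = L["nodes"];
      c.nodes.assign(nodes.begin(), nodes.end());
      for (auto& v : c.nodes) v -= 1;
      c.latched.assign(c.nodes.size(), 0);
      c.neutral.assign(c.nodes.size(), c.standoff);
    }
  }

  std::vector<Tie> ties(ties_in.size());
  for (int q = 0; q < ties_in.size(); ++q) {
    List L = ties_in[q];
    ties[q].sa = (int)L["solid_a"] - 1;
    ties[q].na = (int)L["node_a"] - 1;
    ties[q].sb = (int)L["solid_b"] - 1;
    ties[q].nb = (int)L["node_b"] - 1;
  }

  for (auto& t : ties) {
    Solid& a = so[t.sa];
    if (a.rigid) {
      const Solid& b = so[t.sb];
      const double rx = a.X[t.na] - a.cx0, ry = a.Y[t.na] - a.cy0;
      a.M += b.mass[t.nb];
      a.I += b.mass[t.nb] * (rx * rx + ry * ry);
    }
  }

  std::vector<Landmark> lm(landmarks_in.size());
  for (int q = 0; q < landmarks_in.size(); ++q) {
    List L = landmarks_in[q];
    lm[q].solid = (int)L["solid"] - 1;
    lm[q].node = (int)L["node"] - 1;
    lm[q].surface = (int)L["surface"] - 1;
  }

  if (theta.size() < nsteps + 2)
    stop("theta must provide nsteps + 2 samples");

  // ---- outputs --------------------------------------------------------------
  const int nsamp = nsteps / sample_every + 1;
  const int nlm = lm.size();
  NumericVector t_out(nsamp), theta_out(nsamp);
  NumericMatrix dist_out(nsamp, std::max(nlm, 1));
  const int ns_stress = stress_solid >= 0 ? so[stress_solid].ne : 0;
  NumericMatrix vm_out(nsamp, std::max(ns_stress, 1));
  NumericMatrix sig_max_out(nsamp, 4);
  NumericVector strain_max_out(nsamp), pen_out(nsamp);
  const int nsolid = so.size(), nfluid = fl.size();
  NumericMatrix cent_ux(nsamp, nsolid), cent_uy(nsamp, nsolid);
  NumericMatrix ke_out(nsamp, std::max(nfluid, 1));
  std::vector<List> snaps;

  double pen_running = 0.0;
  std::vector<double> spx, spy;
  SurfGrid sgrid;

  auto record = [&](int row, int step) {
    t_out[row] = step * dt;
    theta_out[row] = theta[step];
    for (int q = 0; q < nlm; ++q) {
      const Solid& s = so[lm[q].solid];
      const Surface& f = sf[lm[q].surface];
      const Solid& ss = so[f.solid];
      const double p[2] = { s.X[lm[q].node] + s.ux[lm[q].node],
                            s.Y[lm[q].node] + s.uy[lm[q].node] };
      double best = std::numeric_limits<double>::max();
      const int ns = (int)f.nodes.size();
      for (int e = 0; e < ns; ++e) {
        const int i = f.nodes[e], j = f.nodes[(e + 1) % ns];
        const double a[2] = { ss.X[i] + ss.ux[i], ss.Y[i] + ss.uy[i] };
        const double b[2] = { ss.X[j] + ss.ux[j], ss.Y[j] + ss.uy[j] };
        double t, cp[2];
        best = std::min(best, fsi::pt_seg(p, a, b, t, cp));
      }
      dist_out(row, q) = best;
    }
    if (stress_solid >= 0) {
      const Solid& s = so[stress_solid];
      double vmmax = -1.0, smax = 0.0;
      int emax = 0;
      for (int e = 0; e < s.ne; ++e) {
        const double vm = fsi::von_mises4(&s.sig[4 * e]);
        vm_out(row, e) = vm;
        if (vm > vmmax) { vmmax = vm; emax = e; }
        const double exx = s.strn[4 * e], eyy = s.strn[4 * e + 1],
                     exy = s.strn[4 * e + 3];
        const double lam = 0.5 * (exx + eyy) +
          std::sqrt(0.25 * (exx - eyy) * (exx - eyy) + exy * exy);
        smax = std::max(smax, lam);
      }
      for (int c = 0; c < 4; ++c) sig_max_out(row, c) = s.sig[4 * emax + c];
      strain_max_out[row] = smax;
    }
    for (int q = 0; q < nsolid; ++q) {
      double sx = 0, sy = 0;
      for (int i = 0; i < so[q].nn; ++i) { sx += so[q].ux[i]; sy += so[q].uy[i]; }
      cent_ux(row, q) = sx / so[q].nn;
      cent_uy(row, q) = sy / so[q].nn;
    }
    for (int q = 0; q < nfluid; ++q) {
      double ke = 0;
      for (int i = 0; i < fl[q].n; ++i)
        ke += 0.5 * fl[q].m[i] *
              (fl[q].vx[i] * fl[q].vx[i] + fl[q].vy[i] * fl[q].vy[i]);
      ke_out(row, q) = ke;
    }
    pen_out[row] = pen_running;
    pen_running = 0.0;
  };

  auto snapshot = [&](int step) {
    List flsnap(nfluid), sosnap(nsolid);
    for (int q = 0; q < nfluid; ++q) {
      const Fluid& f = fl[q];
      NumericMatrix pos(f.n, 2), vel(f.n, 2);
      NumericVector rho(f.n), p(f.n);
      for (int i = 0; i < f.n; ++i) {
        pos(i, 0) = f.x[i]; pos(i, 1) = f.y[i];
        vel(i, 0) = f.vx[i]; vel(i, 1) = f.vy[i];
        rho[i] = f.rho[i]; p[i] = f.p[i];
      }
      flsnap[q] = List::create(_["pos"] = pos, _["vel"] = vel,
                               _["rho"] = rho, _["p"] = p);
    }
    for (int q = 0; q < nsolid; ++q) {
      NumericMatrix u(so[q].nn, 2);
      for (int i = 0; i < so[q].nn; ++i) {
        u(i, 0) = so[q].ux[i]; u(i, 1) = so[q].uy[i];
      }
      sosnap[q] = u;
    }
    snaps.push_back(List::create(_["time"] = step * dt, _["fluids"] = flsnap,
                                 _["solids"] = sosnap));
  };

  // prescribed motion: rigid rotation of rest position about the origin
  auto impose = [&](int step) {
    const double th = theta[step];
    const double thn = theta[step + 1];
    const double c = std::cos(th), s_ = std::sin(th);
    const double cn = std::cos(thn), sn = std::sin(thn);
    for (auto& s : so)
      for (int idx : s.presc) {
        const double X = s.X[idx], Y = s.Y[idx];
        const double px = c * X - s_ * Y, py = s_ * X + c * Y;
        const double qx = cn * X - sn * Y, qy = sn * X + cn * Y;
        s.ux[idx] = px - X; s.uy[idx] = py - Y;
        s.vx[idx] = (qx - px) / dt; s.vy[idx] = (qy - py) / dt;
      }
  };

  impose(0);
  record(0, 0);
  if (snap_every > 0) snapshot(0);


  // ---- time loop ------------------------------------------------------------
  for (int step = 0; step < nsteps; ++step) {
    impose(step);

    // fluid rates: half-neighborhood sweep over the sorted cell grid.
    // Pairwise math identical to fsi::sph_pair (continuity + symmetric
    // pressure gradient + Monaghan viscosity), restructured for speed.
    for (auto& f : fl) {
      if (f.n == 0) continue;
      fluid_grid(f);
      const double h = f.h, supp2 = 4.0 * h * h;
      const double sig = fsi::kernel_sigma(h, 2);
      const bool do_shepard =
        shepard_every > 0 && step > 0 && step % shepard_every == 0;
      // cell-pair offsets covering each unordered pair exactly once
      static const int offs[4][2] = { {1, 0}, {-1, 1}, {0, 1}, {1, 1} };
      if (do_shepard) {
        const double w0 = sig;  // cubic spline at q = 0
        std::vector<double> num(f.n), den(f.n);
        for (int i = 0; i < f.n; ++i) {
          num[i] = f.m[i] * w0;
          den[i] = f.m[i] / f.rho[i] * w0;
        }
        auto shep_pair = [&](int i, int j) {
          const double dx = f.x[i] - f.x[j], dy = f.y[i] - f.y[j];
          const double r2 = dx * dx + dy * dy;
          if (r2 >= supp2) return;
          const double q = std::sqrt(r2) / h;
          const double w = sig * ((q < 1.0)
            ? 1.0 - 1.5 * q * q + 0.75 * q * q * q
            : 0.25 * (2.0 - q) * (2.0 - q) * (2.0 - q));
          num[i] += f.m[j] * w; den[i] += f.m[j] / f.rho[j] * w;
          num[j] += f.m[i] * w; den[j] += f.m[i] / f.rho[i] * w;
        };
        for (int cy = 0; cy < f.gny; ++cy)
          for (int cx = 0; cx < f.gnx; ++cx) {
            const int c = cy * f.gnx + cx;
            const int a0 = f.cell_start[c], a1 = f.cell_start[c + 1];
            for (int a = a0; a < a1; ++a)
              for (int b = a + 1; b < a1; ++b)
                shep_pair(f.order[a], f.order[b]);
            for (auto& o : offs) {
              const int nx2 = cx + o[0], ny2 = cy + o[1];
              if (nx2 < 0 || nx2 >= f.gnx || ny2 >= f.gny) continue;
              const int c2 = ny2 * f.gnx + nx2;
              const int b0 = f.cell_start[c2], b1 = f.cell_start[c2 + 1];
              for (int a = a0; a < a1; ++a)
                for (int b = b0; b < b1; ++b)
                  shep_pair(f.order[a], f.order[b]);
            }
          }
        for (int i = 0; i < f.n; ++i) f.rho[i] = num[i] / den[i];
      }
      for (int i = 0; i < f.n; ++i) {
        f.p[i] = f.c0 * f.c0 * (f.rho[i] - f.rho0);
        f.ax[i] = f.gx; f.ay[i] = f.gy; f.drho[i] = 0.0;
      }
      const double epsh2 = f.eps * h * h;
      auto rate_pair = [&](int i, int j) {
        const double dx = f.x[i] - f.x[j], dy = f.y[i] - f.y[j];
        const double r2 = dx * dx + dy * dy;
        if (r2 >= supp2 || r2 == 0.0) return;
        const double r = std::sqrt(r2);
        const double q = r / h;
        const double fp = (q < 1.0) ? (-3.0 * q + 2.25 * q * q)
                                    : (-0.75 * (2.0 - q) * (2.0 - q));
        const double gradfac = sig * fp / (h * r);
        const double dvx = f.vx[i] - f.vx[j], dvy = f.vy[i] - f.vy[j];
        const double vdotx = dvx * dx + dvy * dy;
        const double cont = vdotx * gradfac;
        f.drho[i] += f.m[j] * cont;
        f.drho[j] += f.m[i] * cont;
        double Pi = 0.0;
        if (vdotx < 0.0) {
          const double mu = h * vdotx / (r2 + epsh2);
          Pi = (-f.alpha * f.c0 * mu + f.beta * mu * mu) /
               (0.5 * (f.rho[i] + f.rho[j]));
        }
        const double fac = (f.p[i] / (f.rho[i] * f.rho[i]) +
                            f.p[j] / (f.rho[j] * f.rho[j]) + Pi) * gradfac;
        f.ax[i] -= f.m[j] * fac * dx; f.ay[i] -= f.m[j] * fac * dy;
        f.ax[j] += f.m[i] * fac * dx; f.ay[j] += f.m[i] * fac * dy;
      };
      for (int cy = 0; cy < f.gny; ++cy)
        for (int cx = 0; cx < f.gnx; ++cx) {
          const int c = cy * f.gnx + cx;
          const int a0 = f.cell_start[c], a1 = f.cell_start[c + 1];
          for (int a = a0; a < a1; ++a)
            for (int b = a + 1; b < a1; ++b)
              rate_pair(f.order[a], f.order[b]);
          for (auto& o : offs) {
            const int nx2 = cx + o[0], ny2 = cy + o[1];
            if (nx2 < 0 || nx2 >= f.gnx || ny2 >= f.gny) continue;
            const int c2 = ny2 * f.gnx + nx2;
            const int b0 = f.cell_start[c2], b1 = f.cell_start[c2 + 1];
            for (int a = a0; a < a1; ++a)
              for (int b = b0; b < b1; ++b)
                rate_pair(f.order[a], f.order[b]);
          }
        }
    }

    // zero solid force accumulators
    for (auto& s : so) {
      std::fill(s.fx.begin(), s.fx.end(), 0.0);
      std::fill(s.fy.begin(), s.fy.end(), 0.0);
    }

    // contact coupling
    for (auto& c : ct) {
      const Surface& f = sf[c.surface];
      Solid& ssurf = so[f.solid];
      surf_positions(ssurf, f, spx, spy);
      const int ns = (int)spx.size();
      sgrid.build(spx, spy, c.reach);
      double bal_x = 0, bal_y = 0;
      const int npts = c.type == 0 ? fl[c.fluid].n : (int)c.nodes.size();
      for (int ii = 0; ii < npts; ++ii) {
        double px, py;
        if (c.type == 0) { px = fl[c.fluid].x[ii]; py = fl[c.fluid].y[ii]; }
        else {
          const int nd = c.nodes[ii];
          px = so[c.solid].X[nd] + so[c.solid].ux[nd];
          py = so[c.solid].Y[nd] + so[c.solid].uy[nd];
        }
        // candidate segments from 3x3 cells of the segment-midpoint grid
        const int cx = sgrid.grid.clampi((int)std::floor((px - sgrid.grid.xmin) / sgrid.grid.cell), 0, sgrid.grid.nx - 1);
        const int cy = sgrid.grid.clampi((int)std::floor((py - sgrid.grid.ymin) / sgrid.grid.cell), 0, sgrid.grid.ny - 1);
        double best = std::numeric_limits<double>::max(), bt = 0, bcp[2] = {0, 0};
        int bseg = -1;
        const double p[2] = { px, py };
        for (int oy = -1; oy <= 1; ++oy)
          for (int ox = -1; ox <= 1; ++ox) {
            const int ncx = cx + ox, ncy = cy + oy;
            if (ncx < 0 || ncx >= sgrid.grid.nx || ncy < 0 || ncy >= sgrid.grid.ny) continue;
            for (int sgi = sgrid.grid.head[(size_t)ncy * sgrid.grid.nx + ncx]; sgi >= 0; sgi = sgrid.grid.nxt[sgi]) {
              const int s2 = (sgi + 1) % ns;
              const double a[2] = { spx[sgi], spy[sgi] };
              const double b[2] = { spx[s2], spy[s2] };
              double t, cp[2];
              const double dd = fsi::pt_seg2(p, a, b, t, cp);
              if (dd < best) { best = dd; bt = t; bseg = sgi; bcp[0] = cp[0]; bcp[1] = cp[1]; }
            }
          }
        if (bseg < 0) continue;
        const int s2 = (bseg + 1) % ns;
        double ex = spx[s2] - spx[bseg], ey = spy[s2] - spy[bseg];
        const double L = std::sqrt(ex * ex + ey * ey);
        if (L == 0.0) continue;
        const double nxv = f.orient * (ey / L), nyv = f.orient * (-ex / L);
        const double sd = (px - bcp[0]) * nxv + (py - bcp[1]) * nyv;
        if (step == 0 && c.tension_range > 0 && !c.latched[ii] &&
            sd < c.standoff + c.tension_range) {
          // initial film: bond force-free at the formation thickness
          c.latched[ii] = 1;
          c.neutral[ii] = std::max(c.standoff, sd);
          continue;
        }
        const double ntr = c.latched[ii] ? c.neutral[ii] : c.standoff;
        const double x = ntr - sd;  // > 0: film thinner than bonded thickness
        double fmag;
        if (x >= 0.0) {
          if (x > c.cap)
            stop("contact penetration %g m exceeds cap %g m at step %d "
                 "(contact stiffness or time step misconfigured)", x, c.cap, step);
          pen_running = std::max(pen_running, x);
          fmag = c.kc * x;
          c.latched[ii] = 1;
        } else if (c.latched[ii] && -x < c.tension_range) {
          const double taper = 1.0 + x / c.tension_range;  // 1 -> 0
          fmag = c.kc * x * taper * taper;
        } else {
          continue;
        }
        const double Fx = fmag * nxv, Fy = fmag * nyv;
        if (c.type == 0) {
          fl[c.fluid].ax[ii] += Fx / fl[c.fluid].m[ii];
          fl[c.fluid].ay[ii] += Fy / fl[c.fluid].m[ii];
        } else {
          so[c.solid].fx[c.nodes[ii]] += Fx;
          so[c.solid].fy[c.nodes[ii]] += Fy;
        }
        const int i1 = f.nodes[bseg], i2 = f.nodes[s2];
        ssurf.fx[i1] -= Fx * (1.0 - bt); ssurf.fy[i1] -= Fy * (1.0 - bt);
        ssurf.fx[i2] -= Fx * bt;         ssurf.fy[i2] -= Fy * bt;
        if (debug) {
          // Newton's third law: point force + distributed reaction cancel
          bal_x += Fx - Fx * (1.0 - bt) - Fx * bt;
          bal_y += Fy - Fy * (1.0 - bt) - Fy * bt;
        }
      }
      if (debug && (std::fabs(bal_x) > 1e-9 || std::fabs(bal_y) > 1e-9))
        stop("fluid-structure force balance violated at step %d", step);
    }

    // solid internal forces + Maxwell advance
    for (auto& s : so) {
      if (s.rigid) continue;
      const int nm = (int)s.modes.size();
      for (int e = 0; e < s.ne; ++e) {
        const int id[3] = { s.t1[e], s.t2[e], s.t3[e] };
        double exx = 0, eyy = 0, exy = 0;
        for (int a = 0; a < 3; ++a) {
          exx += s.dNdx[3 * e + a] * s.ux[id[a]];
          eyy += s.dNdy[3 * e + a] * s.uy[id[a]];
          exy += 0.5 * (s.dNdy[3 * e + a] * s.ux[id[a]] +
                        s.dNdx[3 * e + a] * s.uy[id[a]]);
        }
        const double tr = exx + eyy;
        const double dev[4] = { exx - tr / 3.0, eyy - tr / 3.0, -tr / 3.0, exy };
        double sg[4] = { s.K * tr, s.K * tr, s.K * tr, 0.0 };
        for (int cidx = 0; cidx < 4; ++cidx) sg[cidx] += 2.0 * s.Ginf * dev[cidx];
        double* ep = &s.eprev[4 * e];
        for (int m = 0; m < nm; ++m) {
          double* skp = &s.sk[(size_t)4 * (e * nm + m)];
          for (int cidx = 0; cidx < 4; ++cidx) {
            const double de = dev[cidx] - ep[cidx];
            skp[cidx] = s.modes[m].e1 * skp[cidx] +
                        2.0 * s.modes[m].G * s.modes[m].e2 * de;
            sg[cidx] += skp[cidx];
          }
        }
        for (int cidx = 0; cidx < 4; ++cidx) {
          ep[cidx] = dev[cidx];
          s.sig[4 * e + cidx] = sg[cidx];
        }
        s.strn[4 * e] = exx; s.strn[4 * e + 1] = eyy;
        s.strn[4 * e + 2] = 0.0; s.strn[4 * e + 3] = exy;
        const double A = s.area[e];
        for (int a = 0; a < 3; ++a) {
          s.fx[id[a]] -= A * (s.dNdx[3 * e + a] * sg[0] + s.dNdy[3 * e + a] * sg[3]);
          s.fy[id[a]] -= A * (s.dNdy[3 * e + a] * sg[1] + s.dNdx[3 * e + a] * sg[3]);
        }
      }
    }

    // ties: lump slave force and mass into master (rigid junction)
    for (auto& t : ties) {
      so[t.sa].fx[t.na] += so[t.sb].fx[t.nb];
      so[t.sa].fy[t.na] += so[t.sb].fy[t.nb];
    }

    // integrate solids (semi-implicit Euler, equivalent to central difference)
    for (size_t q = 0; q < so.size(); ++q) {
      Solid& s = so[q];
      if (s.rigid) continue;
      for (int i = 0; i < s.nn; ++i) {
        double mi = s.mass[i];
        // tied masters carry the slave mass; handled below via tie list
        const double axv = s.fx[i] / mi - s.ra * s.vx[i];
        const double ayv = s.fy[i] / mi - s.ra * s.vy[i];
        if (!s.fixedx[i]) { s.vx[i] += axv * dt; s.ux[i] += s.vx[i] * dt; }
        if (!s.fixedy[i]) { s.vy[i] += ayv * dt; s.uy[i] += s.vy[i] * dt; }
      }
    }
    // rigid bodies: total force/torque -> 3-DOF update -> nodal kinematics
    for (auto& s : so) {
      if (!s.rigid) continue;
      double Fx = 0, Fy = 0, T = 0;
      const double cx = s.cx0 + s.cdx, cy = s.cy0 + s.cdy;
      for (int i = 0; i < s.nn; ++i) {
        Fx += s.fx[i]; Fy += s.fy[i];
        const double rx = s.X[i] + s.ux[i] - cx, ry = s.Y[i] + s.uy[i] - cy;
        T += rx * s.fy[i] - ry * s.fx[i];
      }
      s.vcx += (Fx / s.M - s.ra * s.vcx) * dt;
      s.vcy += (Fy / s.M - s.ra * s.vcy) * dt;
      s.omega += (T / s.I - s.ra * s.omega) * dt;
      s.cdx += s.vcx * dt; s.cdy += s.vcy * dt;
      s.phi += s.omega * dt;
      const double cph = std::cos(s.phi), sph = std::sin(s.phi);
      const double ncx = s.cx0 + s.cdx, ncy = s.cy0 + s.cdy;
      for (int i = 0; i < s.nn; ++i) {
        const double rx0 = s.X[i] - s.cx0, ry0 = s.Y[i] - s.cy0;
        const double rx = cph * rx0 - sph * ry0, ry = sph * rx0 + cph * ry0;
        s.ux[i] = ncx + rx - s.X[i];
        s.uy[i] = ncy + ry - s.Y[i];
        s.vx[i] = s.vcx - s.omega * ry;
        s.vy[i] = s.vcy + s.omega * rx;
      }
    }

    // redo tied masters with combined mass, then copy to slaves
    for (auto& t : ties) {
      Solid& a = so[t.sa];
      Solid& b = so[t.sb];
      if (a.rigid) {
        // slave follows the rigid master exactly
        b.vx[t.nb] = a.vx[t.na]; b.vy[t.nb] = a.vy[t.na];
        b.ux[t.nb] = a.ux[t.na]; b.uy[t.nb] = a.uy[t.na];
        continue;
      }
      // undo the master's update and redo with combined mass
      const double mi = a.mass[t.na] + b.mass[t.nb];
      // recover pre-update velocity: v_new = v_old + (f/ma - ra v_old) dt
      // simpler: recompute from stored force with combined mass
      const double v_oldx = (a.vx[t.na] - (a.fx[t.na] / a.mass[t.na]) * dt) /
                            (1.0 - a.ra * dt);
      const double v_oldy = (a.vy[t.na] - (a.fy[t.na] / a.mass[t.na]) * dt) /
                            (1.0 - a.ra * dt);
      const double u_oldx = a.ux[t.na] - a.vx[t.na] * dt;
      const double u_oldy = a.uy[t.na] - a.vy[t.na] * dt;
      const double axv = a.fx[t.na] / mi - a.ra * v_oldx;
      const double ayv = a.fy[t.na] / mi - a.ra * v_oldy;
      a.vx[t.na] = v_oldx + axv * dt; a.vy[t.na] = v_oldy + ayv * dt;
      a.ux[t.na] = u_oldx + a.vx[t.na] * dt; a.uy[t.na] = u_oldy + a.vy[t.na] * dt;
      b.vx[t.nb] = a.vx[t.na]; b.vy[t.nb] = a.vy[t.na];
      b.ux[t.nb] = a.ux[t.na]; b.uy[t.nb] = a.uy[t.na];
    }

    // re-impose prescribed positions at the end-of-step time
    {
      const double thn = theta[step + 1];
      const double th = theta[step];
      const double cn = std::cos(thn), sn = std::sin(thn);
      const double c = std::cos(th), s_ = std::sin(th);
      for (auto& s : so)
        for (int idx : s.presc) {
          const double X = s.X[idx], Y = s.Y[idx];
          const double qx = cn * X - sn * Y, qy = sn * X + cn * Y;
          const double px = c * X - s_ * Y, py = s_ * X + c * Y;
          s.ux[idx] = qx - X; s.uy[idx] = qy - Y;
          s.vx[idx] = (qx - px) / dt; s.vy[idx] = (qy - py) / dt;
        }
    }

    // integrate fluids
    for (auto& f : fl)
      for (int i = 0; i < f.n; ++i) {
        f.vx[i] += f.ax[i] * dt;
        f.vy[i] += f.ay[i] * dt;
        f.rho[i] += f.drho[i] * dt;
        f.x[i] += f.vx[i] * dt;
        f.y[i] += f.vy[i] * dt;
      }

    // stability monitoring
    if ((step + 1) % 20 == 0 || step + 1 == nsteps) {
      bool bad = false;
      for (auto& f : fl)
        for (int i = 0; i < f.n && !bad; ++i)
          if (!std::isfinite(f.x[i]) || !std::isfinite(f.vx[i]) ||
              std::fabs(f.x[i]) > 10.0 || std::fabs(f.y[i]) > 10.0 ||
              !std::isfinite(f.rho[i]) || f.rho[i] <= 0.0) bad = true;
      for (auto& s : so)
        for (int i = 0; i < s.nn && !bad; ++i)
          if (!std::isfinite(s.ux[i]) || !std::isfinite(s.vx[i]) ||
              std::fabs(s.ux[i]) > 10.0) bad = true;
      if (bad)
        stop("numerical instability detected at step %d (NaN or nonpositive density)",
             step + 1);
    }

    if ((step + 1) % sample_every == 0) record((step + 1) / sample_every, step + 1);
    if (snap_every > 0 && (step + 1) % snap_every == 0) snapshot(step + 1);
    if ((step + 1) % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  // ---- final state ----------------------------------------------------------
  List flout(nfluid), soout(nsolid);
  for (int q = 0; q < nfluid; ++q) {
    const Fluid& f = fl[q];
    NumericMatrix pos(f.n, 2), vel(f.n, 2);
    NumericVector rho(f.n), p(f.n);
    for (int i = 0; i < f.n; ++i) {
      pos(i, 0) = f.x[i]; pos(i, 1) = f.y[i];
      vel(i, 0) = f.vx[i]; vel(i, 1) = f.vy[i];
      rho[i] = f.rho[i]; p[i] = f.p[i];
    }
    flout[q] = List::create(_["pos"] = pos, _["vel"] = vel, _["rho"] = rho,
                            _["p"] = p);
  }
  for (int q = 0; q < nsolid; ++q) {
    NumericMatrix u(so[q].nn, 2), v(so[q].nn, 2);
    for (int i = 0; i < so[q].nn; ++i) {
      u(i, 0) = so[q].ux[i]; u(i, 1) = so[q].uy[i];
      v(i, 0) = so[q].vx[i]; v(i, 1) = so[q].vy[i];
    }
    soout[q] = List::create(_["u"] = u, _["v"] = v);
  }

  return List::create(
    _["t"] = t_out, _["theta"] = theta_out, _["dist"] = dist_out,
    _["vm"] = vm_out, _["sig_at_max"] = sig_max_out,
    _["strain_max"] = strain_max_out, _["pen_max"] = pen_out,
    _["cent_ux"] = cent_ux, _["cent_uy"] = cent_uy, _["ke"] = ke_out,
    _["fluids"] = flout, _["solids"] = soout,
    _["snapshots"] = wrap(snaps));
}
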